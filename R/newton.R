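## Damped Newton with forward-difference Jacobian and step-halving line
## search. `fn` returns a residual vector (may contain non-finite values,
## treated as infinitely bad). Deterministic given inputs.
newton_solve <- function(fn, x0, tol_fun, max_iter = 120, max_halvings = 30) {
  x <- x0
  r <- fn(x)
  if (any(!is.finite(r))) {
    return(list(x = x, residuals = r, converged = FALSE, iterations = 0L))
  }
  n <- length(x)
  for (iter in seq_len(max_iter)) {
    if (tol_fun(r)) {
      return(list(x = x, residuals = r, converged = TRUE, iterations = iter - 1L))
    }
    J <- matrix(0, length(r), n)
    for (j in seq_len(n)) {
      h <- 1e-7 * max(1, abs(x[j]))
      xj <- x
      xj[j] <- xj[j] + h
      rj <- fn(xj)
      if (any(!is.finite(rj))) {
        xj[j] <- x[j] - h
        rj <- fn(xj)
        h <- -h
      }
      J[, j] <- (rj - r) / h
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      step <- tryCatch(qr.solve(J, -r, tol = 1e-14), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
    }
    norm0 <- sum(r^2)
    lambda <- 1
    accepted <- FALSE
    for (k in seq_len(max_halvings)) {
      xn <- x + lambda * step
      rn <- fn(xn)
      if (all(is.finite(rn)) && sum(rn^2) < norm0) {
        x <- xn
        r <- rn
        accepted <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!accepted) break
  }
  list(x = x, residuals = r, converged = tol_fun(r), iterations = max_iter)
}
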