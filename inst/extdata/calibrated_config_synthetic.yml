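surface:
  specific_surface_area_m2_g: 96.0
  sites:
  - name: FeOH
    density_nm2: 3.45
    logK_H: 9.300000000000001
  - name: Fe3O
    density_nm2: 2.7
    logK_H: 9.300000000000001
  logK_Na: -1.0
  logK_Cl: -1.0
edl:
  topology: extended
  C1_F_m2: 0.9
  C2_F_m2: 0.74
  d_ST_m: 8.0e-10
  temperature_K: 295.149999999999977
  relative_permittivity: 78.5
nom:
  HA:
    nica:
      Qmax1_mol_kg: 3.15
      logK1: 2.93
      m1: 0.5
      Qmax2_mol_kg: 2.55
      logK2: 8.0
      m2: 0.26
    q: 0.1
    M_w_original_kDa: 17.0
    M_o_kDa: 1.6
    k_fractionation_kDa: 15.4
    rho_p_kg_m3: 1250.0
    V_limit_m3_m2: 3.0e-09
    charge_split_first_plane: 0.5
    affinity_offset_J_kg: 27539.90910835269824
    affinity_offset_J_mol: 0.0
  FA:
    nica:
      Qmax1_mol_kg: 5.88
      logK1: 2.34
      m1: 0.38
      Qmax2_mol_kg: 1.86
      logK2: 8.6
      m2: 0.53
    q: 0.3
    M_w_original_kDa: 1.8
    M_o_kDa: 1.8
    k_fractionation_kDa: 0.0
    rho_p_kg_m3: 1250.0
    V_limit_m3_m2: 8.0e-10
    charge_split_first_plane: 0.8
    affinity_offset_J_kg: 68409.539592663713847
    affinity_offset_J_mol: 0.0
affinity:
  ligand_exchange_kJ_mol: 10.0
regulator:
  steepness_R: 1.0
  steepness_theta: 1.0
  override: ~
volume:
  omega_basis: volume
  V_constant_m3_m2: 3.0e-09
scenario: variable
solver:
  tol_charge_C_m2: 9.999999999999999e-12
  tol_partition: 1.0e-10
  max_iter: 120.0
  damping: 0.5
experiment:
  solid_g_L: 1.0
  ionic_strength_M: 0.01
  pH_values:
  - 4.0
  - 6.0
  ExpI_fixed_FA_mg_L: 100.0
  ExpI_HA_series_mg_L:
  - 20.0
  - 50.0
  - 80.0
  - 110.0
  - 145.0
  - 180.0
  - 210.0
  - 240.0
  ExpII_fixed_HA_mg_L: 160.0
  ExpII_FA_series_mg_L:
  - 25.0
  - 50.0
  - 75.0
  - 100.0
  - 125.0
  - 150.0
  - 175.0
  - 200.0
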