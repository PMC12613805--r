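design_id,pH,HA_added_mg_L,FA_added_mg_L,HA_ads_mg_m2,FA_ads_mg_m2,HA_sol_mg_L,FA_sol_mg_L,V_m3_m2,M_w_HA_ads_kDa,M_w_mix_kDa,scenario,mode,converged
ExpI,4,0,0,0,0,0,0,1.9e-9,17,NA,variable,predictive,TRUE
ExpI,4,20,0,0.20833333333333334,0,0,0,3e-9,17,17,variable,predictive,TRUE
ExpI,4,50,0,0.5121288686207287,0,0.8356286124100478,0,3e-9,17,17,variable,predictive,TRUE
ExpI,4,80,0,0.8333333333333334,0,0,0,3e-9,17,17,variable,predictive,TRUE
ExpI,4,110,0,1.1458333333333333,0,0,0,3e-9,17,17,variable,predictive,TRUE
ExpI,4,145,0,1.4856316842297683,0,2.379358313942248,0,3e-9,17,17,variable,predictive,TRUE
ExpI,4,180,0,1.875,0,0,0,3e-9,16.999996446851103,16.999996446851103,variable,predictive,TRUE
ExpI,4,210,0,2.108811619904364,0,7.554084489181037,0,3e-9,16.229999995472774,16.229999995472774,variable,predictive,TRUE
ExpI,4,240,0,2.1081383996724457,0,37.61871363144522,0,3e-9,14.438291564582725,14.438291564582725,variable,predictive,TRUE
ExpI,4,0,100,0,0.9313832037246917,0,10.587212442429589,8e-10,17,1.8,variable,predictive,TRUE
ExpI,4,20,100,0.20833333333333334,0.8792856580030415,0,15.588576831708025,1.2238905429134088e-9,16.999999941825937,4.728698285283809,variable,predictive,TRUE
ExpI,4,50,100,0.5208333333333334,0.7547014857802519,0,27.54865736509582,1.7064335997449872e-9,16.99996785737704,8.062618900441075,variable,predictive,TRUE
ExpI,4,80,100,0.8220022767441102,0.6201141601010904,1.0877814325654214,40.46904063029532,2.0595184791276683e-9,16.981717010335775,10.49166050882035,variable,predictive,TRUE
ExpI,4,110,100,0.8988392866407652,0.5982414924613675,23.71142848248654,42.56881672370872,2.153783533011515e-9,14.240288942341794,9.455208325476162,variable,predictive,TRUE
ExpI,4,145,100,0.9501938686240767,0.5959812003889711,53.781388612088634,42.78580476265878,2.144524499313743e-9,11.074874048025126,7.468316084372278,variable,predictive,TRUE
ExpI,4,180,100,0.9120173750435832,0.5889901945973405,92.44633199581602,43.45694131865531,2.1307317655086235e-9,9.097440448178899,6.2140617324087035,variable,predictive,TRUE
ExpI,4,210,100,0.8998626321172354,0.6042836455841631,123.61318731674541,41.98877002392034,2.1199241766850905e-9,7.937084911545302,5.482039431417237,variable,predictive,TRUE
ExpI,4,240,100,0.9059805200034524,0.5899476639518118,153.02587007966855,43.36502426062607,2.1104641971639962e-9,7.077443807078964,4.9435914371462895,variable,predictive,TRUE
ExpI,6,0,0,0,0,0,0,1.9e-9,17,NA,variable,predictive,TRUE
ExpI,6,20,0,0.20833333333333334,0,0,0,3e-9,17,17,variable,predictive,TRUE
ExpI,6,50,0,0.5208333333333334,0,0,0,3e-9,17,17,variable,predictive,TRUE
ExpI,6,80,0,0.8333333333333334,0,0,0,3e-9,17,17,variable,predictive,TRUE
ExpI,6,110,0,1.1458333333333333,0,0,0,3e-9,16.99999999998469,16.99999999998469,variable,predictive,TRUE
ExpI,6,145,0,1.2747257218571433,0,22.626330701714238,0,3e-9,15.135463584542048,15.135463584542048,variable,predictive,TRUE
ExpI,6,180,0,1.3489555890985325,0,50.500263446540885,0,3e-9,12.543757452177795,12.543757452177795,variable,predictive,TRUE
ExpI,6,210,0,1.3321003083608614,0,82.11837039735731,0,3e-9,10.988525492899509,10.988525492899509,variable,predictive,TRUE
ExpI,6,240,0,1.3299682092878988,0,112.32305190836172,0,3e-9,9.818211377328305,9.818211377328305,variable,predictive,TRUE
ExpI,6,0,100,0,0.839226397178354,0,19.434265870878022,8e-10,17,1.8,variable,predictive,TRUE
ExpI,6,20,100,0.20634102239167715,0.7254622547098563,0.19126185039899468,30.355623547853796,1.285140898646461e-9,16.999998578573123,5.151882259015408,variable,predictive,TRUE
ExpI,6,50,100,0.5208333333333334,0.5733623449166629,0,44.95721488800036,1.8483077039707539e-9,16.97328547367194,9.030123662089922,variable,predictive,TRUE
ExpI,6,80,100,0.6589921390618202,0.4927913514411709,16.736754650065265,52.69203026164759,2.024342658754238e-9,13.456004511996719,8.286792524849757,variable,predictive,TRUE
ExpI,6,110,100,0.6484639209710389,0.5225476890263331,47.74746358678027,49.83542185347203,2.0350756124396555e-9,10.333308636789974,6.590582450327263,variable,predictive,TRUE
ExpI,6,145,100,0.6594106143342736,0.5072534544635703,81.69658102390973,51.30366837149725,2.0409409147552383e-9,8.271532396251564,5.450358787123898,variable,predictive,TRUE
ExpI,6,180,100,0.6571558305154642,0.5260882469114858,116.91304027051544,49.49552829649736,2.045477772425645e-9,7.0032543343417935,4.7456989171364095,variable,predictive,TRUE
ExpI,6,210,100,0.6424468013210664,0.5077663798195537,148.32510707317763,51.25442753732284,2.049038290360628e-9,6.250917283156095,4.326984597222664,variable,predictive,TRUE
ExpI,6,240,100,0.6578043859833348,0.49470891804960254,176.85077894559987,52.507943867238154,2.0524471298698693e-9,5.685988276062787,4.012270392301272,variable,predictive,TRUE
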