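design_id,pH,HA_added_mg_L,FA_added_mg_L,HA_ads_mg_m2,FA_ads_mg_m2,HA_sol_mg_L,FA_sol_mg_L,V_m3_m2,M_w_HA_ads_kDa,M_w_mix_kDa,scenario,mode,converged
ExpII,4,0,0,0,0,0,0,1.9e-9,17,NA,variable,predictive,TRUE
ExpII,4,0,25,0,0.2601077427254626,0,0.029656698355587707,8e-10,17,1.8,variable,predictive,TRUE
ExpII,4,0,50,0,0.5208333333333334,0,0,8e-10,17,1.8,variable,predictive,TRUE
ExpII,4,0,75,0,0.78125,0,0,8e-10,17,1.8,variable,predictive,TRUE
ExpII,4,0,100,0,0.9416426659564131,0,9.602304068184338,8e-10,17,1.8,variable,predictive,TRUE
ExpII,4,0,125,0,0.9438279550598193,0,34.39251631425735,8e-10,17,1.8,variable,predictive,TRUE
ExpII,4,0,150,0,0.963535881206164,0,57.50055540420826,8e-10,17,1.8,variable,predictive,TRUE
ExpII,4,0,175,0,0.9619464548781178,0,82.65314033170068,8e-10,17,1.8,variable,predictive,TRUE
ExpII,4,0,200,0,0.9390257891894578,0,109.85352423781205,8e-10,17,1.8,variable,predictive,TRUE
ExpII,4,160,0,1.6564870537613599,0,0.9772428389094614,0,3e-9,16.99999999999912,16.99999999999912,variable,predictive,TRUE
ExpII,4,160,25,1.6364373077207877,0.2604166666666667,2.9020184588043776,0,2.690118898622883e-9,16.276915047737628,14.23776851158495,variable,predictive,TRUE
ExpII,4,160,50,1.0909608191754128,0.5208333333333334,55.267761359160374,0,2.2923734721324013e-9,11.602489908419395,8.44953450007758,variable,predictive,TRUE
ExpII,4,160,75,0.9405464447904178,0.5766641426346676,69.70754130011989,19.640242307071915,2.1691283274169124e-9,10.399987334674536,7.152039216058899,variable,predictive,TRUE
ExpII,4,160,100,0.8812980525274525,0.6039034559891957,75.39538695736456,42.02526822503721,2.1385657038742107e-9,10.120605694771552,6.862580644764386,variable,predictive,TRUE
ExpII,4,160,125,0.9256775814934337,0.6069443763238841,71.13495217663036,66.73333987290712,2.1212167914277657e-9,9.96505859215153,6.703551143155524,variable,predictive,TRUE
ExpII,4,160,150,0.8928917000970218,0.6007474667453598,74.28239679068591,92.32824319244546,2.1091056648607363e-9,9.857740310385605,6.594742493773864,variable,predictive,TRUE
ExpII,4,160,175,0.8845650613889866,0.6169939205630484,75.08175410665729,115.76858362594736,2.0998059871957553e-9,9.776028608319702,6.512404426881172,variable,predictive,TRUE
ExpII,4,160,200,0.8942917999675809,0.6026249775796001,74.14798720311224,142.1480021523584,2.0922600558521275e-9,9.710162922877071,6.446357991143888,variable,predictive,TRUE
ExpII,6,0,0,0,0,0,0,1.9e-9,17,NA,variable,predictive,TRUE
ExpII,6,0,25,0,0.2604166666666667,0,0,8e-10,17,1.8,variable,predictive,TRUE
ExpII,6,0,50,0,0.5170081096201405,0,0.3672214764665114,8e-10,17,1.8,variable,predictive,TRUE
ExpII,6,0,75,0,0.7649347214181333,0,1.5662667438592024,8e-10,17,1.8,variable,predictive,TRUE
ExpII,6,0,100,0,0.8483137798419805,0,18.561877135169865,8e-10,17,1.8,variable,predictive,TRUE
ExpII,6,0,125,0,0.8395850712573034,0,44.39983315929888,8e-10,17,1.8,variable,predictive,TRUE
ExpII,6,0,150,0,0.8840405140371428,0,65.13211065243429,8e-10,17,1.8,variable,predictive,TRUE
ExpII,6,0,175,0,0.8440006030564354,0,93.9759421065822,8e-10,17,1.8,variable,predictive,TRUE
ExpII,6,0,200,0,0.8571927840132267,0,117.70949273473023,8e-10,17,1.8,variable,predictive,TRUE
ExpII,6,160,0,1.2914927618624057,0,36.01669486120906,0,3e-9,13.895052680406117,13.895052680406117,variable,predictive,TRUE
ExpII,6,160,25,1.041266830252377,0.2565448380594155,60.038384295771806,0.37169554629610957,2.563239089294845e-9,11.314202440174075,9.425369839081512,variable,predictive,TRUE
ExpII,6,160,50,0.7227347348992236,0.4683045424004377,90.61746544967454,5.042763929557985,2.1325900807618614e-9,8.222710828540198,5.690382155324755,variable,predictive,TRUE
ExpII,6,160,75,0.6904879207809518,0.47680237535353776,93.71315960502864,29.226971966060376,2.067385020770803e-9,7.811324399038261,5.263028408334155,variable,predictive,TRUE
ExpII,6,160,100,0.6545583251291164,0.5198281296502375,97.16240078760482,50.0964995535772,2.0429623503507e-9,7.660577984942176,5.1111262666260435,variable,predictive,TRUE
ExpII,6,160,125,0.6509691376914859,0.5129303754368106,97.50696278161735,75.75868395806617,2.0279309129467174e-9,7.568677098873376,5.019789516597457,variable,predictive,TRUE
ExpII,6,160,150,0.6381454423925103,0.5383313854409963,98.73803753031902,98.32018699766435,2.017091502506384e-9,7.502815912701523,4.954931267139641,variable,predictive,TRUE
ExpII,6,160,175,0.6158496821802457,0.5243971811733403,100.8784305106964,124.65787060735933,2.0086253202961747e-9,7.45161141169182,4.90485484211161,variable,predictive,TRUE
ExpII,6,160,200,0.6235464313499847,0.5149376318723767,100.13954259040148,150.56598734025184,2.001685060289563e-9,7.409789648030811,4.864182005184396,variable,predictive,TRUE
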