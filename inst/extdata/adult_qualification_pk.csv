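dose_mg_kg,id,auc_last_pred,auc_last_obs,cmax_pred,cmax_obs,half_life_pred,half_life_obs
0.2,010,138,174,3.5,3.5,NA,NA
0.2,011,96,84,4.3,3.1,NA,NA
1.0,014,1944,2464,21.9,30.1,369,340
1.0,015,1977,2471,22.3,29.9,364,258
5.0,017,12030,18780,113.4,126.1,369,513
5.0,019,11155,13817,104.2,145.0,366,248
5.0,020,9697,12431,88.8,103.7,376,249
5.0,022,12353,11246,113.5,119.6,373,419
15.0,023,34716,37101,322.6,363.3,353,332
15.0,025,37096,24014,322.3,274.8,369,420
15.0,026,33580,39658,317.9,402.9,363,472
15.0,027,28933,20119,264.7,217.8,375,401
20.0,029,40082,45555,349.0,524.4,371,496
20.0,031,43846,42466,413.1,454.2,367,424
20.0,033,43729,44423,411.9,482.4,359,437
20.0,034,40271,44046,374.1,366.9,361,437
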