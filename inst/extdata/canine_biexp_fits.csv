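group,dog,a_pct,b_per_hour,c_pct,d_per_hour,t_half_short_printed,t_half_long_printed
epicardial,1,37.9,0.3712,62.1,0.0012930,1.87,537
epicardial,2,16.0,0.4705,84.0,0.0017590,1.47,394
epicardial,3,NA,NA,100,0.0005308,NA,1306
epicardial,4,19.8,1.004,80.2,0.0005354,0.69,1295
epicardial,5,29.2,0.291,70.8,0.0003566,2.38,1944
epicardial,6,29.6,0.2413,70.4,0.0002413,2.87,2873
epicardial,7,29.4,0.4448,70.6,0.0008787,1.56,789
epicardial,8,28.2,0.4850,71.8,0.0005060,1.43,1370
epicardial,9,36.6,0.3662,63.4,0.0006483,1.89,1069
endocardial,1,40.7,0.3407,59.3,0.0013530,2.03,512
endocardial,2,31.5,0.2468,68.5,0.0006903,2.81,1004
endocardial,3,21.8,2.7770,78.2,0.0012670,0.25,547
endocardial,4,29.7,0.3896,70.3,0.0006643,1.78,1043
endocardial,5,33.1,0.4293,66.9,0.0004125,1.61,1680
endocardial,6,49.9,0.2316,50.1,0.0007734,2.99,896
endocardial,7,25.0,1.1510,75.0,0.000840,0.60,825
endocardial,8,37.6,0.4884,62.4,0.0001245,1.42,5567
endocardial,9,63.0,0.1564,37.0,0.0003590,4.43,1931
endocardial,10,51.3,0.1858,48.7,0.0004166,3.73,1664
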