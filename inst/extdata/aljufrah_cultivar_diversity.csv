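cultivar,N,Na,Ne,Hobs,Hexp,UHexp,F,P_pct
Abel,23,1.938,1.767,0.747,0.379,0.387,-0.973,75.00
Bamour,7,2.813,2.121,0.653,0.491,0.530,-0.329,100.00
Berni,21,2.625,1.733,0.622,0.348,0.356,-0.790,87.50
Bestian,33,2.750,1.684,0.629,0.339,0.344,-0.855,93.75
Deglet,25,1.688,1.630,0.625,0.314,0.320,-0.992,62.50
Halima,15,1.750,1.750,0.750,0.375,0.388,-1.000,75.00
Hamria,34,3.313,2.049,0.915,0.497,0.504,-0.842,100.00
Kathari,34,2.500,1.861,0.807,0.425,0.432,-0.897,93.75
Noyat Meka,9,2.563,1.755,0.576,0.365,0.387,-0.578,93.75
Omglaib,12,1.563,1.563,0.563,0.281,0.293,-1.000,56.25
Saiedi,21,1.813,1.813,0.813,0.406,0.416,-1.000,81.25
Saila,11,1.625,1.625,0.625,0.313,0.327,-1.000,62.50
Sokeri,19,5.125,3.630,0.708,0.656,0.674,-0.079,100.00
Tagiat,39,1.813,1.813,0.813,0.406,0.412,-1.000,81.25
Talis,25,1.625,1.625,0.625,0.313,0.319,-1.000,62.50
Tameg,22,2.750,1.833,0.685,0.380,0.389,-0.802,81.25
Tasferit,13,3.938,2.124,0.630,0.478,0.497,-0.319,100.00
Zebur,14,1.625,1.625,0.625,0.313,0.324,-1.000,62.50
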