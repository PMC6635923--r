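species,pop,n_nuc,n_cp,lat,lon
jishanensis,WHA,36,8,36.520,109.342
jishanensis,XNA,16,7,35.941,110.396
jishanensis,XNB,39,10,35.930,110.404
jishanensis,XNC,20,7,35.992,110.392
jishanensis,JSA,31,10,35.634,110.966
jishanensis,JSB,35,13,35.616,110.950
jishanensis,JYA,25,15,35.261,112.078
jishanensis,HRA,6,6,34.435,110.069
jishanensis,HLA,21,10,34.490,109.988
jishanensis,YJA,26,13,34.834,110.431
qiui,BWL,26,13,33.399,110.637
qiui,NBL,29,13,33.673,111.041
qiui,KYPL,16,5,32.980,109.376
qiui,KYL,36,14,32.980,109.358
qiui,SBL,5,3,31.736,110.600
qiui,KZL,6,5,32.449,111.455
rockii,DLZ,29,5,31.687,111.3477
rockii,BHZ,10,3,32.209,111.202
rockii,SGZ,10,8,31.736,110.600
rockii,LCZ,4,4,33.931,111.211
rockii,MYZ,9,6,33.690,106.170
rockii,WXZ,10,8,33.027,104.752
rockii,LDZ,10,8,34.151,106.520
rockii,LBZ,11,3,33.833,107.094
rockii,MPZ,10,8,34.005075,107.315
rockii,GYZ,5,3,33.727,107.419
rockii,XJZ,6,3,33.724,107.385
rockii,ZXZ,10,10,34.631,104.676
rockii,DSZ,6,4,34.571,105.717
rockii,HSZ,10,10,36.007,108.653
rockii,YAZ,3,3,36.537,109.342
rockii,CBZ,10,8,35.082,108.725
rockii,GQZ,10,9,36.277,109.365
rockii,AFZ,10,9,36.128,109.198
rockii,BMZ,7,4,34.053,107.646
rockii,LHZ,4,4,34.053,107.900
rockii,PMZ,5,3,34.053,107.890
rockii,HGZ,6,5,34.096,107.679
rockii,MHZ,9,8,34.093,107.719
rockii,XSZ,10,8,35.073,108.593
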