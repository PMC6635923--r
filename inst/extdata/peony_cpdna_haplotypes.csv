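species,pop,haplotype,count
jishanensis,WHA,H10,8
jishanensis,XNA,H10,7
jishanensis,XNB,H10,10
jishanensis,XNC,H10,7
jishanensis,JSA,H10,10
jishanensis,JSB,H10,13
jishanensis,JYA,H10,1
jishanensis,JYA,H11,14
jishanensis,HRA,H9,6
jishanensis,HLA,H9,10
jishanensis,YJA,H10,13
qiui,BWL,H6,13
qiui,NBL,H6,13
qiui,KYPL,H12,5
qiui,KYL,H12,14
qiui,SBL,H2,1
qiui,SBL,H17,2
qiui,KZL,H2,1
qiui,KZL,H13,4
rockii,DLZ,H2,1
rockii,DLZ,H8,4
rockii,BHZ,H2,1
rockii,BHZ,H3,1
rockii,BHZ,H4,1
rockii,SGZ,H2,8
rockii,LCZ,H15,4
rockii,MYZ,H4,1
rockii,MYZ,H12,5
rockii,WXZ,H18,8
rockii,LDZ,H12,8
rockii,LBZ,H5,2
rockii,LBZ,H14,1
rockii,MPZ,H5,7
rockii,MPZ,H8,1
rockii,GYZ,H5,3
rockii,XJZ,H5,3
rockii,ZXZ,H4,1
rockii,ZXZ,H12,9
rockii,DSZ,H4,4
rockii,HSZ,H1,1
rockii,HSZ,H7,9
rockii,YAZ,H8,3
rockii,CBZ,H7,8
rockii,GQZ,H8,9
rockii,AFZ,H1,9
rockii,BMZ,H5,4
rockii,LHZ,H16,4
rockii,PMZ,H16,3
rockii,HGZ,H1,5
rockii,MHZ,H1,7
rockii,MHZ,H5,1
rockii,XSZ,H7,8
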