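ID,TIME,EVID,AMT,DRUG,DV,MDV,SEX,DM,BSA
1,0,0,.,.,5.21,0,1,0,1.65
1,0,1,288.75,paclitaxel,.,1,1,0,1.65
1,1,1,123.75,cisplatin,.,1,1,0,1.65
1,11,0,.,.,1.42,0,1,0,1.65
1,28,0,.,.,4.05,0,1,0,1.65
1,28,1,288.75,paclitaxel,.,1,1,0,1.65
1,29,1,123.75,cisplatin,.,1,1,0,1.65
1,39,0,.,.,0.93,0,1,0,1.65
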