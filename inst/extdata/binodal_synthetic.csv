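nacl_mM,csat,cden
50,30,300
100,18,320
150,11,340
200,7,350
300,3.5,360
400,1.8,370
500,1.0,380
750,0.5,390
1000,0.35,400
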