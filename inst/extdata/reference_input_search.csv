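model_no,substrate,product,AIC,AICc,BIC
II,PI3K,PI3K_p,8788,8844,9126
1,Akt,Akt_pS473,1127,1185,1469
2,Akt_pT308,Akt_pT308_pS473,1535,1593,1877
3,PDK1_cyt,PDK1_mem,8595,8653,8937
4,Akt,Akt_pT308,8597,8655,8939
5,TSC2,TSC2_pT1462,8599,8657,8941
6,PRAS40,PRAS40_pT246,8623,8681,8965
7,PRAS40,PRAS40_pS183,8663,8721,9005
8,p70_S6K,p70_S6K_pT389,8667,8724,9009
9,PRAS40_pS183,PRAS40_pT246_pS183,8704,8761,9045
10,p70_S6K,p70_S6K_pT229,8706,8763,9048
11,IR_beta,IR_beta_pY1146,8733,8791,9075
12,IRS1,IRS1_loc_pS636,8734,8791,9076
13,IRS1,IRS1_loc,8738,8795,9080
14,4EBP1,4EBP1_pT37_46,8762,8820,9104
15,PRAS40_pS183,PRAS40,8763,8821,9105
16,p70_S6K_pT229,p70_S6K_pT229_pT389,8768,8826,9110
17,p70_S6K_pT389,p70_S6K_pT229_pT389,8776,8834,9118
18,Akt_pT308_pS473,Akt_pT308,8777,8835,9119
19,Akt_pT308_pS473,Akt_pS473,8781,8839,9123
20,PRAS40_pT246,PRAS40_pT246_pS183,8781,8839,9123
21,IRS1_loc,IRS1_loc_pS636,8781,8839,9123
22,TSC2_pT1462,TSC2,8781,8839,9123
23,PI3K_p,PI3K,8781,8839,9123
24,PDK1_mem,PDK1_cyt,8781,8839,9123
25,p70_S6K_pT229,p70_S6K,8781,8839,9123
26,IR_beta_pY1146,IR_beta,8782,8840,9124
27,Akt_pS473,Akt_pT308_pS473,8783,8841,9125
28,PRAS40_pT246,PRAS40,8788,8846,9130
29,PRAS40_pT246_pS183,PRAS40_pS183,8788,8846,9130
30,4EBP1_pT37_46,4EBP1,8790,8848,9132
31,PRAS40_pT246_pS183,PRAS40_pT246,8790,8848,9132
32,p70_S6K_pT229_pT389,p70_S6K_pT389,8791,8849,9133
33,Akt_pS473,Akt,8791,8849,9133
34,Akt_pT308,Akt,8797,8855,9139
35,IRS1_loc_pS636,IRS1,8799,8857,9141
36,p70_S6K_pT389,p70_S6K,8799,8857,9141
37,p70_S6K_pT229_pT389,p70_S6K_pT229,8803,8861,9145
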