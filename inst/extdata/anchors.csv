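vmax_r4,vmax_r15,k1,observable,target,weight
1,0.01,NA,FC,22.1333,1
2,0.01,NA,FC,22.2205,1
3,0.01,NA,FC,22.2485,1
4,0.01,NA,FC,22.2623,1
5,0.01,NA,FC,22.2705,1
1,0.02,NA,FC,9.93711,1
2,0.02,NA,FC,9.96287,1
3,0.02,NA,FC,9.97106,1
4,0.02,NA,FC,9.97509,1
5,0.02,NA,FC,9.97749,1
1,0.03,NA,FC,4.75843,1
2,0.03,NA,FC,4.76165,1
3,0.03,NA,FC,4.76266,1
4,0.03,NA,FC,4.76315,1
5,0.03,NA,FC,4.76345,1
1,0.04,NA,FC,2.83914,1
2,0.04,NA,FC,2.8396,1
3,0.04,NA,FC,2.83975,1
4,0.04,NA,FC,2.83981,1
5,0.04,NA,FC,2.83985,1
1,0.05,NA,FC,1.99568,1
2,0.05,NA,FC,1.99583,1
3,0.05,NA,FC,1.99587,1
4,0.05,NA,FC,1.99589,1
5,0.05,NA,FC,1.9959,1
1,0.01,NA,CE,0.084617,1
2,0.01,NA,CE,0.084669,1
3,0.01,NA,CE,0.084685,1
4,0.01,NA,CE,0.084693,1
5,0.01,NA,CE,0.084698,1
1,0.02,NA,CE,0.14247,1
2,0.02,NA,CE,0.142576,1
3,0.02,NA,CE,0.14261,1
4,0.02,NA,CE,0.142627,1
5,0.02,NA,CE,0.142637,1
1,0.03,NA,CE,0.162901,1
2,0.03,NA,CE,0.162953,1
3,0.03,NA,CE,0.162969,1
4,0.03,NA,CE,0.162976,1
5,0.03,NA,CE,0.162981,1
1,0.04,NA,CE,0.166003,1
2,0.04,NA,CE,0.166019,1
3,0.04,NA,CE,0.166024,1
4,0.04,NA,CE,0.166026,1
5,0.04,NA,CE,0.166028,1
1,0.05,NA,CE,0.166386,1
2,0.05,NA,CE,0.166394,1
3,0.05,NA,CE,0.166397,1
4,0.05,NA,CE,0.166398,1
5,0.05,NA,CE,0.166399,1
1,0.01,NA,LDLC,0.08454,1
2,0.01,NA,LDLC,0.084591,1
3,0.01,NA,LDLC,0.084608,1
4,0.01,NA,LDLC,0.084616,1
5,0.01,NA,LDLC,0.084621,1
1,0.02,NA,LDLC,0.14232,1
2,0.02,NA,LDLC,0.142428,1
3,0.02,NA,LDLC,0.142462,1
4,0.02,NA,LDLC,0.142479,1
5,0.02,NA,LDLC,0.142489,1
1,0.03,NA,LDLC,0.162786,1
2,0.03,NA,LDLC,0.162839,1
3,0.03,NA,LDLC,0.162855,1
4,0.03,NA,LDLC,0.162863,1
5,0.03,NA,LDLC,0.162867,1
1,0.04,NA,LDLC,0.165925,1
2,0.04,NA,LDLC,0.165941,1
3,0.04,NA,LDLC,0.165947,1
4,0.04,NA,LDLC,0.165949,1
5,0.04,NA,LDLC,0.16595,1
1,0.05,NA,LDLC,0.166317,1
2,0.05,NA,LDLC,0.166326,1
3,0.05,NA,LDLC,0.166328,1
4,0.05,NA,LDLC,0.166329,1
5,0.05,NA,LDLC,0.16633,1
1,0.01,NA,LDLR,34335.9,0.25
2,0.01,NA,LDLR,34334,0.25
3,0.01,NA,LDLR,34333.4,0.25
4,0.01,NA,LDLR,34333.1,0.25
5,0.01,NA,LDLR,34332.9,0.25
1,0.02,NA,LDLR,34530.3,0.25
2,0.02,NA,LDLR,34527,0.25
3,0.02,NA,LDLR,34526,0.25
4,0.02,NA,LDLR,34525.5,0.25
5,0.02,NA,LDLR,34525.2,0.25
1,0.03,NA,LDLR,34770.5,0.25
2,0.03,NA,LDLR,34766.7,0.25
3,0.03,NA,LDLR,34765.4,0.25
4,0.03,NA,LDLR,34764.8,0.25
5,0.03,NA,LDLR,34764.4,0.25
1,0.04,NA,LDLR,34998.3,0.25
2,0.04,NA,LDLR,34994.4,0.25
3,0.04,NA,LDLR,34993.2,0.25
4,0.04,NA,LDLR,34992.5,0.25
5,0.04,NA,LDLR,34992.2,0.25
1,0.05,NA,LDLR,35192,0.25
2,0.05,NA,LDLR,35188.2,0.25
3,0.05,NA,LDLR,35187,0.25
4,0.05,NA,LDLR,35186.4,0.25
5,0.05,NA,LDLR,35186,0.25
NA,NA,NA,ACoA,32.13,1
NA,NA,0.2,ACoA,57.52,1
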