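nest_id,bird_id,role,motif_id,element_index,label,onset_s,offset_s
N01,T01,tutor,m01,1,A,0.000000,0.025449
N01,T01,tutor,m01,2,B,0.042415,0.064756
N01,T01,tutor,m01,3,C,0.079649,0.127465
N01,T01,tutor,m01,4,D,0.159343,0.244039
N01,T01,tutor,m01,5,E,0.300503,0.323816
N01,T01,tutor,m01,6,F,0.339358,0.369241
N01,T01,tutor,m01,7,G,0.389163,0.408041
N01,T01,tutor,m01,8,H,0.420626,0.439753
N01,T01,tutor,m01,9,I,0.452505,0.486443
N01,T01,tutor,m02,1,A,0.000000,0.028698
N01,T01,tutor,m02,2,B,0.047831,0.067327
N01,T01,tutor,m02,3,C,0.080325,0.105514
N01,T01,tutor,m02,4,D,0.122307,0.187238
N01,T01,tutor,m02,5,E,0.230525,0.244040
N01,T01,tutor,m02,6,F,0.253050,0.312628
N01,T01,tutor,m02,7,G,0.352346,0.374869
N01,T01,tutor,m02,8,H,0.389884,0.418791
N01,T01,tutor,m02,9,I,0.438062,0.470917
N01,T01,tutor,m03,1,A,0.000000,0.030881
N01,T01,tutor,m03,2,B,0.051469,0.064787
N01,T01,tutor,m03,3,C,0.073666,0.107122
N01,T01,tutor,m03,4,D,0.129425,0.192310
N01,T01,tutor,m03,5,E,0.234233,0.254109
N01,T01,tutor,m03,6,F,0.267359,0.332344
N01,T01,tutor,m03,7,G,0.375668,0.402826
N01,T01,tutor,m03,8,H,0.420931,0.442115
N01,T01,tutor,m03,9,I,0.456237,0.490455
N01,U01.1,tutee,m01,1,A,0.000000,0.017400
N01,U01.1,tutee,m01,2,B,0.029001,0.043677
N01,U01.1,tutee,m01,3,C,0.053462,0.113165
N01,U01.1,tutee,m01,4,D,0.152967,0.192329
N01,U01.1,tutee,m01,5,E,0.218571,0.231474
N01,U01.1,tutee,m01,6,F,0.240077,0.291028
N01,U01.1,tutee,m01,7,G,0.324995,0.336431
N01,U01.1,tutee,m01,8,H,0.344055,0.368044
N01,U01.1,tutee,m01,9,I,0.384036,0.412839
N01,U01.1,tutee,m02,1,A,0.000000,0.016788
N01,U01.1,tutee,m02,2,B,0.027979,0.054370
N01,U01.1,tutee,m02,3,C,0.071964,0.123162
N01,U01.1,tutee,m02,4,D,0.157293,0.206523
N01,U01.1,tutee,m02,5,E,0.239343,0.255549
N01,U01.1,tutee,m02,6,F,0.266353,0.303448
N01,U01.1,tutee,m02,7,G,0.328178,0.342355
N01,U01.1,tutee,m02,8,H,0.351806,0.361527
N01,U01.1,tutee,m02,9,I,0.368007,0.395608
N01,U01.1,tutee,m03,1,A,0.000000,0.017849
N01,U01.1,tutee,m03,2,B,0.029749,0.054947
N01,U01.1,tutee,m03,3,C,0.071746,0.134514
N01,U01.1,tutee,m03,4,D,0.176360,0.223684
N01,U01.1,tutee,m03,5,E,0.255233,0.277927
N01,U01.1,tutee,m03,6,F,0.293057,0.321333
N01,U01.1,tutee,m03,7,G,0.340183,0.365130
N01,U01.1,tutee,m03,8,H,0.381761,0.402006
N01,U01.1,tutee,m03,9,I,0.415503,0.446666
N01,U01.2,tutee,m01,1,A,0.000000,0.131349
N01,U01.2,tutee,m01,2,n1,0.218915,0.229963
N01,U01.2,tutee,m01,3,n2,0.237328,0.249195
N01,U01.2,tutee,m01,4,n3,0.257106,0.293753
N01,U01.2,tutee,m01,5,n4,0.318185,0.373475
N01,U01.2,tutee,m01,6,n5,0.410335,0.459575
N01,U01.2,tutee,m02,1,A,0.000000,0.032798
N01,U01.2,tutee,m02,2,n1,0.054664,0.097651
N01,U01.2,tutee,m02,3,n2,0.126310,0.141966
N01,U01.2,tutee,m02,4,n3,0.152403,0.170837
N01,U01.2,tutee,m02,5,n4,0.183126,0.210364
N01,U01.2,tutee,m02,6,n5,0.228523,0.255946
N01,U01.2,tutee,m03,1,A,0.000000,0.018218
N01,U01.2,tutee,m03,2,n1,0.030363,0.063612
N01,U01.2,tutee,m03,3,n2,0.085778,0.103867
N01,U01.2,tutee,m03,4,n3,0.115926,0.128273
N01,U01.2,tutee,m03,5,n4,0.136505,0.179205
N01,U01.2,tutee,m03,6,n5,0.207672,0.232592
N02,T02,tutor,m01,1,A,0.000000,0.010494
N02,T02,tutor,m01,2,B,0.017491,0.036771
N02,T02,tutor,m01,3,C,0.049625,0.085022
N02,T02,tutor,m01,4,D,0.108621,0.143936
N02,T02,tutor,m01,5,E,0.167479,0.247993
N02,T02,tutor,m01,6,F,0.301669,0.322154
N02,T02,tutor,m01,7,G,0.335810,0.369392
N02,T02,tutor,m02,1,A,0.000000,0.009518
N02,T02,tutor,m02,2,B,0.015864,0.050963
N02,T02,tutor,m02,3,C,0.074363,0.150336
N02,T02,tutor,m02,4,D,0.200984,0.262344
N02,T02,tutor,m02,5,E,0.303250,0.364056
N02,T02,tutor,m02,6,F,0.404594,0.426397
N02,T02,tutor,m02,7,G,0.440932,0.485025
N02,T02,tutor,m03,1,A,0.000000,0.025306
N02,T02,tutor,m03,2,B,0.042177,0.054334
N02,T02,tutor,m03,3,C,0.062439,0.121127
N02,T02,tutor,m03,4,D,0.160252,0.211084
N02,T02,tutor,m03,5,E,0.244973,0.285082
N02,T02,tutor,m03,6,F,0.311821,0.343852
N02,T02,tutor,m03,7,G,0.365206,0.401726
N02,U02.1,tutee,m01,1,A,0.000000,0.023526
N02,U02.1,tutee,m01,2,B,0.039210,0.071753
N02,U02.1,tutee,m01,3,C,0.093448,0.135109
N02,U02.1,tutee,m01,4,D,0.162883,0.221910
N02,U02.1,tutee,m01,5,n1,0.261261,0.290141
N02,U02.1,tutee,m01,6,n2,0.309394,0.336053
N02,U02.1,tutee,m01,7,n3,0.353826,0.399483
N02,U02.1,tutee,m01,8,n4,0.429922,0.446082
N02,U02.1,tutee,m01,9,n5,0.456855,0.471937
N02,U02.1,tutee,m01,10,n6,0.481992,0.531418
N02,U02.1,tutee,m01,11,n7,0.564369,0.580635
N02,U02.1,tutee,m01,12,n8,0.591478,0.623741
N02,U02.1,tutee,m02,1,A,0.000000,0.026571
N02,U02.1,tutee,m02,2,B,0.044285,0.062225
N02,U02.1,tutee,m02,3,C,0.074184,0.110305
N02,U02.1,tutee,m02,4,D,0.134386,0.179343
N02,U02.1,tutee,m02,5,n1,0.209314,0.223296
N02,U02.1,tutee,m02,6,n2,0.232617,0.265526
N02,U02.1,tutee,m02,7,n3,0.287465,0.325782
N02,U02.1,tutee,m02,8,n4,0.351326,0.368768
N02,U02.1,tutee,m02,9,n5,0.380396,0.401707
N02,U02.1,tutee,m02,10,n6,0.415915,0.451346
N02,U02.1,tutee,m02,11,n7,0.474967,0.505548
N02,U02.1,tutee,m02,12,n8,0.525935,0.554623
N02,U02.1,tutee,m03,1,A,0.000000,0.026468
N02,U02.1,tutee,m03,2,B,0.044113,0.064969
N02,U02.1,tutee,m03,3,C,0.078873,0.142320
N02,U02.1,tutee,m03,4,D,0.184618,0.232497
N02,U02.1,tutee,m03,5,n1,0.264416,0.285511
N02,U02.1,tutee,m03,6,n2,0.299574,0.318489
N02,U02.1,tutee,m03,7,n3,0.331099,0.373229
N02,U02.1,tutee,m03,8,n4,0.401316,0.415345
N02,U02.1,tutee,m03,9,n5,0.424698,0.445689
N02,U02.1,tutee,m03,10,n6,0.459682,0.490285
N02,U02.1,tutee,m03,11,n7,0.510687,0.522379
N02,U02.1,tutee,m03,12,n8,0.530174,0.559093
N02,U02.2,tutee,m01,1,A,0.000000,0.013157
N02,U02.2,tutee,m01,2,B,0.021928,0.034477
N02,U02.2,tutee,m01,3,C,0.042843,0.076144
N02,U02.2,tutee,m01,4,D,0.098344,0.139248
N02,U02.2,tutee,m01,5,E,0.166517,0.212247
N02,U02.2,tutee,m01,6,F,0.242734,0.273348
N02,U02.2,tutee,m01,7,G,0.293758,0.323134
N02,U02.2,tutee,m02,1,A,0.000000,0.029858
N02,U02.2,tutee,m02,2,B,0.049763,0.067598
N02,U02.2,tutee,m02,3,C,0.079488,0.172003
N02,U02.2,tutee,m02,4,D,0.233680,0.294028
N02,U02.2,tutee,m02,5,E,0.334259,0.382145
N02,U02.2,tutee,m02,6,F,0.414069,0.437427
N02,U02.2,tutee,m02,7,G,0.453000,0.498300
N02,U02.2,tutee,m03,1,A,0.000000,0.014488
N02,U02.2,tutee,m03,2,B,0.024146,0.035823
N02,U02.2,tutee,m03,3,C,0.043608,0.073590
N02,U02.2,tutee,m03,4,D,0.093577,0.135185
N02,U02.2,tutee,m03,5,E,0.162923,0.220767
N02,U02.2,tutee,m03,6,F,0.259329,0.275957
N02,U02.2,tutee,m03,7,G,0.287042,0.315746
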