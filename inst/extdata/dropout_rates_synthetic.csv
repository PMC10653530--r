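y
0.329153
0.265388
0.092103
0.170645
0.418176
0.454942
0.03458
0.027784
0.106768
0.119713
0.241056
0.260219
0.001306
0.253218
0.066055
0.145352
0.105119
0.040286
0.0952
0.2921
0.158256
0.013479
0.141574
0.029966
0.087896
0.027395
0.352717
0.499989
0.025532
0.224162
0.10777
0.143987
0.300637
0.064101
0.164634
0.152717
0.149754
0.355266
0.214784
0.085759
0.193115
0.016431
0.142319
0.150067
0.263635
0.140131
0.21201
0.256062
0.130308
0.217316
0.027701
0.155791
0.091073
0.402708
0.045558
0.164409
0.003739
0.148008
0.089341
0.010385
0.133431
0.039882
0.391032
0.020078
0.386224
0.016956
0.32113
0.191763
0.048837
0.185898
0.01391
0.130311
0.062427
0.185316
0.341359
0.124846
0.172625
0.158653
0.219729
0.089533
0.070326
0.343207
0.024639
0.387711
0.239039
0.143036
0.115422
0.162387
0.052318
0.0211
0.163302
0.097029
0.287415
0.432966
0.287412
0.324194
0.308924
0.259962
0.114028
0.015091
0.319793
0.398341
0.156847
0.535209
0.186657
0.222376
0.354463
0.254112
0.264872
0.374754
0.168367
0.068332
0.353604
0.465935
0.111016
0.297847
0.070345
0.024805
0.210438
0.13946
0.168704
0.095222
0.151853
0.202413
0.113632
0.010895
0.065616
0.110188
0.334117
0.036372
0.020074
0.154012
0.329527
0.340474
0.050744
0.451379
0.291442
0.053598
0.035392
0.078536
0.253725
0.31847
0.084757
0.042391
0.303765
0.345372
0.082572
0.328807
0.323036
0.001919
0.214689
0.16099
0.141526
0.167916
0.104656
0.02529
0.033113
0.056574
0.15702
0.286322
0.130465
0.192985
0.436612
0.286717
0.173881
0.045334
0.173216
0.523678
0.186408
0.26445
0.08695
0.115577
0.156204
0.150189
0.175925
0.068724
0.336269
0.134041
0.369691
0.235328
0.473777
0.64178
0.011281
0.066262
0.239417
0.012192
0.133406
0.23109
0.152067
0.048966
0.197278
0.339858
0.347257
0.145347
0.320034
0.495012
0.091138
0.186312
0.1818
0.22145
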