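# Synthetic reference translocation PMF for the QQQ-helix substrate
# (gate open), generated with the bundled synthetic scaffold at
# lambda = 0.60. Stand-in for an externally derived reference
# profile; used by examples and the lambda-fitting defaults.
# z_sigma  F_eps
-3 -0.07937829298
-2.75 -0.1495745337
-2.5 -0.2426432421
-2.25 -0.3234052026
-2 -0.3585018488
-1.75 -0.3245134596
-1.5 -0.1668468408
-1.25 -0.1636126965
-1 -0.1691004641
-0.75 0.1387980688
-0.5 0.4922418819
-0.25 0.7644825532
0 0.8565273647
0.25 0.7723019795
0.5 0.4953026035
0.75 0.1321288795
1 -0.1622989343
1.25 -0.1511278897
1.5 -0.161861774
1.75 -0.3244597373
2 -0.3575589277
2.25 -0.3226933062
2.5 -0.2439342402
2.75 -0.1516650855
3 -0.08096503936
3.25 -0.03874014918
3.5 -0.01700226686
3.75 -0.006154210745
4 -0.001073172866
4.25 0.0005060822601
4.5 0.0005670906059
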