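# Synthetic reference translocation PMF for the QQQ-helix substrate
# (gate closed), generated with the bundled synthetic scaffold at
# lambda = 0.55. Stand-in for an externally derived reference
# profile; used by examples and the lambda-fitting defaults.
# z_sigma  F_eps
-3 -0.08097021668
-2.75 -0.1511457972
-2.5 -0.2414378361
-2.25 -0.3172594052
-2 -0.3557026518
-1.75 -0.323641069
-1.5 -0.1326084149
-1.25 -0.1404420867
-1 -0.2782888913
-0.75 -0.03674912422
-0.5 0.3070436687
-0.25 0.6837342746
0 0.8233986042
0.25 0.6769917996
0.5 0.3037835836
0.75 -0.03514951696
1 -0.2737135654
1.25 -0.133788049
1.5 -0.1314499939
1.75 -0.3249549079
2 -0.3536134006
2.25 -0.3157805746
2.5 -0.2423540034
2.75 -0.1529358043
3 -0.08235923763
3.25 -0.03959378652
3.5 -0.01741148946
3.75 -0.006302092696
4 -0.001097959911
4.25 0.0005186361769
4.5 0.0005793237337
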