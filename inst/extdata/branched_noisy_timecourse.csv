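time,X1,X2,X3,X4
0,1.3122965,3.0668435,1.4881941,0.3782992
0.27586207,0.9142811,3.1472094,1.7368798,0.32612641
0.55172414,0.47927838,3.1680907,2.3834258,0.23119474
0.82758621,0.42004271,2.6561123,2.5490568,0.16409671
1.1034483,0.31915509,1.9860253,2.4737745,0.14916138
1.3793103,0.2748349,1.9555457,2.7122292,0.12744172
1.6551724,0.3259853,1.8137279,2.1052325,0.10534544
1.9310345,0.35791334,1.8153459,2.8051143,0.11768286
2.2068966,0.38051716,2.0279995,2.3683619,0.11464086
2.4827586,0.37256451,2.0066535,2.7355973,0.13006353
2.7586207,0.46323936,1.884244,2.3008513,0.1325671
3.0344828,0.42842528,1.9148559,2.0212593,0.14506169
3.3103448,0.3892488,2.1408679,2.3092871,0.13256555
3.5862069,0.32145992,2.1355787,1.9842035,0.14822969
3.862069,0.45459472,1.8912171,1.9281809,0.13572334
4.137931,0.40237178,1.8862878,2.2835111,0.16977261
4.4137931,0.40004382,2.0975777,2.1301764,0.15367708
4.6896552,0.43612054,2.1713379,2.2347594,0.15576324
4.9655172,0.43018054,1.9873333,2.2528386,0.14788731
5.2413793,0.42105211,2.1821523,2.1036161,0.16623262
5.5172414,0.43443751,2.0828484,2.1063552,0.13328353
5.7931034,0.4296583,1.879908,2.2009398,0.1358711
6.0689655,0.40205199,2.071244,2.4918473,0.16300179
6.3448276,0.3200352,1.7775739,1.8885395,0.13340864
6.6206897,0.42454491,2.2922258,2.3596805,0.13980968
6.8965517,0.39761719,2.4029712,2.3014295,0.13719985
7.1724138,0.39361719,1.9326149,2.4642582,0.1382486
7.4482759,0.34097686,1.797031,2.1600015,0.13882315
7.7241379,0.38057395,2.1208933,2.3105183,0.14984789
8,0.41630859,1.979382,2.2878321,0.1402411
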