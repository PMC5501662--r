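"length_um","density"
1,0.14090971
1.1,0.17268994
1.2,0.20254177
1.3,0.22941276
1.4,0.25264378
1.5,0.2719074
1.6,0.28713544
1.7,0.29844919
1.8,0.30609885
1.9,0.31041428
2,0.31176714
2.1,0.31054285
2.2,0.30712095
2.3,0.301862
2.4,0.29509948
2.5,0.28713544
2.6,0.27823879
2.7,0.26864545
2.8,0.25855972
2.9,0.24815637
3,0.23758318
3.1,0.22696364
3.2,0.21639966
3.3,0.20597421
3.4,0.19575378
3.5,0.18579065
3.6,0.17612491
3.7,0.16678638
3.8,0.15779612
3.9,0.14916797
4,0.14090971
4.1,0.13302419
4.2,0.12551021
4.3,0.11836334
4.4,0.11157657
4.5,0.10514092
4.6,0.09904585
4.7,0.09327972
4.8,0.08783012
4.9,0.08268409
5,0.07782842
5.1,0.07324977
5.2,0.06893487
5.3,0.06487061
5.4,0.06104412
5.5,0.0574429
5.6,0.05405481
5.7,0.05086813
5.8,0.04787162
5.9,0.04505448
6,0.04240641
6.1,0.0399176
6.2,0.03757869
6.3,0.03538082
6.4,0.03331559
6.5,0.03137504
6.6,0.02955165
6.7,0.02783832
6.8,0.02622836
6.9,0.02471546
7,0.02329368
7.1,0.02195743
7.2,0.02070147
7.3,0.01952083
7.4,0.0184109
7.5,0.01736731
7.6,0.01638597
7.7,0.01546304
7.8,0.01459493
7.9,0.01377826
8,0.01300986
8.1,0.01228677
8.2,0.01160619
8.3,0.01096553
8.4,0.01036234
8.5,0.00979432
8.6,0.00925933
8.7,0.00875536
8.8,0.00828052
8.9,0.00783305
9,0.00741127
9.1,0.00701366
9.2,0.00663873
9.3,0.00628515
9.4,0.00595161
9.5,0.00563693
9.6,0.00533998
9.7,0.00505971
9.8,0.00479512
9.9,0.00454528
10,0.00430934
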