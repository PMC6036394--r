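# Synthetic 2D anisotropy function F(r,theta) for an Ir-192 line source.
# Stand-in table: unity on the transverse axis (theta = 90 deg), smooth dip
# toward the source long axis (theta = 0/180 deg); NOT a published dataset.
# Columns: r_mm  theta_deg  F (dimensionless).
1      0      0.640400
1      10     0.653903
1      20     0.692189
1      30     0.749016
1      40     0.815305
1      50     0.880879
1      60     0.936431
1      70     0.975399
1      80     0.995481
1      90     1.000000
1      100    0.995481
1      110    0.975399
1      120    0.936431
1      130    0.880879
1      140    0.815305
1      150    0.749016
1      160    0.692189
1      170    0.653903
1      180    0.640400
2      0      0.640800
2      10     0.654288
2      20     0.692531
2      30     0.749295
2      40     0.815511
2      50     0.881011
2      60     0.936502
2      70     0.975427
2      80     0.995487
2      90     1.000000
2      100    0.995487
2      110    0.975427
2      120    0.936502
2      130    0.881011
2      140    0.815511
2      150    0.749295
2      160    0.692531
2      170    0.654288
2      180    0.640800
5      0      0.642000
5      10     0.655443
5      20     0.693559
5      30     0.750133
5      40     0.816127
5      50     0.881409
5      60     0.936714
5      70     0.975509
5      80     0.995502
5      90     1.000000
5      100    0.995502
5      110    0.975509
5      120    0.936714
5      130    0.881409
5      140    0.816127
5      150    0.750133
5      160    0.693559
5      170    0.655443
5      180    0.642000
10     0      0.644000
10     10     0.657367
10     20     0.695270
10     30     0.751529
10     40     0.817154
10     50     0.882072
10     60     0.937067
10     70     0.975646
10     80     0.995527
10     90     1.000000
10     100    0.995527
10     110    0.975646
10     120    0.937067
10     130    0.882072
10     140    0.817154
10     150    0.751529
10     160    0.695270
10     170    0.657367
10     180    0.644000
15     0      0.646000
15     10     0.659292
15     20     0.696982
15     30     0.752924
15     40     0.818181
15     50     0.882734
15     60     0.937421
15     70     0.975782
15     80     0.995552
15     90     1.000000
15     100    0.995552
15     110    0.975782
15     120    0.937421
15     130    0.882734
15     140    0.818181
15     150    0.752924
15     160    0.696982
15     170    0.659292
15     180    0.646000
20     0      0.648000
20     10     0.661217
20     20     0.698694
20     30     0.754320
20     40     0.819209
20     50     0.883397
20     60     0.937775
20     70     0.975919
20     80     0.995577
20     90     1.000000
20     100    0.995577
20     110    0.975919
20     120    0.937775
20     130    0.883397
20     140    0.819209
20     150    0.754320
20     160    0.698694
20     170    0.661217
20     180    0.648000
30     0      0.652000
30     10     0.665067
30     20     0.702118
30     30     0.757112
30     40     0.821263
30     50     0.884722
30     60     0.938482
30     70     0.976193
30     80     0.995627
30     90     1.000000
30     100    0.995627
30     110    0.976193
30     120    0.938482
30     130    0.884722
30     140    0.821263
30     150    0.757112
30     160    0.702118
30     170    0.665067
30     180    0.652000
50     0      0.660000
50     10     0.672767
50     20     0.708966
50     30     0.762696
50     40     0.825372
50     50     0.887372
50     60     0.939896
50     70     0.976740
50     80     0.995728
50     90     1.000000
50     100    0.995728
50     110    0.976740
50     120    0.939896
50     130    0.887372
50     140    0.825372
50     150    0.762696
50     160    0.708966
50     170    0.672767
50     180    0.660000
75     0      0.670000
75     10     0.682391
75     20     0.717526
75     30     0.769675
75     40     0.830508
75     50     0.890684
75     60     0.941664
75     70     0.977424
75     80     0.995853
75     90     1.000000
75     100    0.995853
75     110    0.977424
75     120    0.941664
75     130    0.890684
75     140    0.830508
75     150    0.769675
75     160    0.717526
75     170    0.682391
75     180    0.670000
100    0      0.680000
100    10     0.692016
100    20     0.726086
100    30     0.776655
100    40     0.835644
100    50     0.893997
100    60     0.943431
100    70     0.978108
100    80     0.995979
100    90     1.000000
100    100    0.995979
100    110    0.978108
100    120    0.943431
100    130    0.893997
100    140    0.835644
100    150    0.776655
100    160    0.726086
100    170    0.692016
100    180    0.680000
150    0      0.700000
150    10     0.711265
150    20     0.743205
150    30     0.790614
150    40     0.845916
150    50     0.900622
150    60     0.946967
150    70     0.979477
150    80     0.996230
150    90     1.000000
150    100    0.996230
150    110    0.979477
150    120    0.946967
150    130    0.900622
150    140    0.845916
150    150    0.790614
150    160    0.743205
150    170    0.711265
150    180    0.700000
200    0      0.720000
200    10     0.730514
200    20     0.760325
200    30     0.804573
200    40     0.856189
200    50     0.907247
200    60     0.950503
200    70     0.980845
200    80     0.996482
200    90     1.000000
200    100    0.996482
200    110    0.980845
200    120    0.950503
200    130    0.907247
200    140    0.856189
200    150    0.804573
200    160    0.760325
200    170    0.730514
200    180    0.720000
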