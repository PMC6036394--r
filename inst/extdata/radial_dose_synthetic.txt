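# Synthetic radial dose function g_L(r) for an Ir-192 line source (L = 3.5 mm).
# Stand-in table with the qualitative shape of published consensus data
# (near unity over 1-100 mm, slow falloff beyond); NOT a published dataset.
# Columns: r_mm  g  (dimensionless, g(10 mm) = 1 exactly).
1      0.992895
5      0.996408
10     1.000000
20     1.004798
30     1.006820
40     1.006462
50     1.004023
60     0.999718
80     0.986014
100    0.965813
120    0.938962
140    0.905058
160    0.863817
180    0.815440
200    0.760986
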