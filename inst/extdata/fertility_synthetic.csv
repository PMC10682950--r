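age,rate
12,0.00122198961921
13,0.00198693147618
14,0.0031422050863
15,0.00483306269857
16,0.00723013814782
17,0.0105197889316
18,0.014886881156
19,0.0204897510067
20,0.0274287429655
21,0.0357117714094
22,0.0452223519558
23,0.0556969178313
24,0.0667183725684
25,0.0777313105643
26,0.0880811143208
27,0.0970746592843
28,0.10405554158
29,0.108482782842
30,         0.11
31,0.108482782842
32,0.10405554158
33,0.0970746592843
34,0.0880811143208
35,0.0777313105643
36,0.0667183725684
37,0.0556969178313
38,0.0452223519558
39,0.0357117714094
40,0.0274287429655
41,0.0204897510067
42,0.014886881156
43,0.0105197889316
44,0.00723013814782
45,0.00483306269857
46,0.0031422050863
47,0.00198693147618
48,0.00122198961921
49,0.000730951241102
50,0.000425251215342
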