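image,predicted,true_count
1,400,416
2,411,437
3,432,432
4,430,432
5,453,446
6,243,245
7,262,257
8,265,248
9,255,262
10,257,262
11,256,264
12,259,264
13,399,406
14,426,447
15,235,229
16,255,256
17,453,446
18,420,429
19,402,429
20,251,263
21,415,443
22,419,452
23,258,269
24,468,472
25,259,269
26,454,472
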