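compound_id,pic50,pic50_calc,activity_class
1,8.699,8.255,High-activity
2,7.602,7.871,Low-activity
3,8.155,7.769,High-activity
4,8.699,8.784,High-activity
5,7.602,7.886,Low-activity
6,6.108,5.638,Low-activity
7,6.45,6.125,Low-activity
8,5,5.342,Low-activity
9,7.137,6.108,Low-activity
10,5,6.704,Low-activity
11,5.89,3.37,Low-activity
12,5.206,5.37,Low-activity
13,5.339,4.533,Low-activity
14,7.959,7.643,High-activity
15,7.328,7.825,Low-activity
16,7.114,7.258,Low-activity
17,5.9,6.05,Low-activity
18,5.862,5.163,Low-activity
19,5.431,6.451,Low-activity
20,5.522,6.439,Low-activity
21,5.289,5.481,Low-activity
22,7.721,6.644,High-activity
23,8.301,7.494,High-activity
24,5,5.355,Low-activity
25,5.759,5.94,Low-activity
26,5,4.957,Low-activity
27,9.301,9.301,High-activity
28,9.097,8.755,High-activity
29,7.824,7.63,High-activity
30,8.398,7.526,High-activity
31,8.699,7.277,High-activity
32,6.541,7.866,Low-activity
33,6.541,6.917,Low-activity
34,7.796,7.635,High-activity
35,5,4.572,Low-activity
36,7.357,7.323,Low-activity
37,7.051,6.647,Low-activity
38,7.357,7.368,Low-activity
39,8.398,8.331,High-activity
40,8.523,8.252,High-activity
41,8.523,8.962,High-activity
42,8.222,8.654,High-activity
43,7.854,8.311,High-activity
44,7.699,9.41,High-activity
45,8,7.422,High-activity
46,7.114,7.299,Low-activity
47,8.046,6.612,High-activity
48,8.699,8.915,High-activity
49,8.523,8.462,High-activity
50,8.699,8.342,High-activity
51,9,7.799,High-activity
52,8.523,8.293,High-activity
53,7.77,8.583,High-activity
54,8.699,9.277,High-activity
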