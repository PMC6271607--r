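frame,t,psi_x,psi_y,psi_z,x,y,z,state
0,0,0.14164,-0.07835,0.08467,0.1371,-0.05647,0.08481,1
1,0.0454545454545455,0.13214,-0.0121,0.10442,0.14966,-0.04204,0.08161,1
2,0.0909090909090909,0.19863,-0.00521,0.14364,0.18757,-0.04297,0.14247,1
3,0.136363636363636,0.18622,0.03488,0.23346,0.17738,-0.00259,0.21141,1
4,0.181818181818182,0.12018,-0.05211,0.203,0.12856,-0.01069,0.20739,1
5,0.227272727272727,0.10151,0.0429,0.12556,0.14159,-0.0186,0.1273,1
6,0.272727272727273,0.08438,0.05165,0.13252,0.06336,0.02114,0.11805,1
7,0.318181818181818,0.02466,0.01433,0.18446,0.00803,0.01514,0.15467,1
8,0.363636363636364,0.03846,0.02288,0.10953,0.06354,0.00177,0.14692,1
9,0.409090909090909,-0.03909,-0.01388,0.12662,0.00874,0.01526,0.12762,1
10,0.454545454545455,0.02793,0.00247,0.1567,0.02178,0.03536,0.15883,1
11,0.5,-0.00749,0.05014,0.08429,0.00286,0.04867,0.10706,1
12,0.545454545454545,-0.01281,-0.01453,0.00324,-0.02039,0.02143,0.03427,1
13,0.590909090909091,-0.05724,0.03225,0.00446,-0.01842,0.02655,0.02338,1
14,0.636363636363636,-0.02402,0.04288,-0.00027,0.00475,0.00394,-0.01787,4
15,0.681818181818182,0.0632,-0.05117,0.01318,0.03063,-0.02015,0.02567,1
16,0.727272727272727,0.02866,-0.02208,0.01183,0.01655,7e-05,0.03538,1
17,0.772727272727273,0.0103,0.04792,0.05966,-0.00729,0.04652,0.05476,1
18,0.818181818181818,0.05014,0.02208,0.03814,-0.00432,0.05261,0.07524,1
19,0.863636363636364,0.00238,-0.04946,0.11521,-0.00148,-0.03796,0.08383,1
20,0.909090909090909,-0.07227,-0.00463,0.08684,-0.01224,-0.03082,0.10137,1
21,0.954545454545455,0.03958,-0.0218,0.14632,0.02957,-0.05089,0.14065,1
22,1,0.07329,-0.0065,0.16994,0.03815,-0.01801,0.16841,1
23,1.04545454545455,0.11949,-0.10351,0.16568,0.05771,-0.04796,0.16569,1
24,1.09090909090909,0.03222,-0.07556,0.2036,0.07352,-0.07394,0.14932,1
25,1.13636363636364,0.05286,-0.01607,0.13855,0.08738,-0.04801,0.1633,1
26,1.18181818181818,0.03621,-0.0539,0.24328,0.05739,-0.0783,0.20891,1
27,1.22727272727273,0.03082,-0.07793,0.20622,0.06244,-0.07221,0.20527,1
28,1.27272727272727,0.00509,-0.13196,0.17367,0.02446,-0.05096,0.19872,1
29,1.31818181818182,0.01242,-0.01935,0.22144,0.01799,-0.02118,0.2235,1
30,1.36363636363636,0.02219,-0.01706,0.26551,0.05822,-0.03428,0.24311,1
31,1.40909090909091,0.15775,-0.06412,0.20439,0.09664,-0.0655,0.21715,1
32,1.45454545454545,0.06222,-0.10088,0.1964,0.05899,-0.1056,0.21957,1
33,1.5,0.0731,-0.05256,0.25565,0.07562,-0.06551,0.25107,1
34,1.54545454545455,0.05756,-0.02,0.26062,0.04269,-0.00811,0.23096,1
35,1.59090909090909,0.04502,0.01911,0.22507,0.0439,-0.02019,0.22727,1
36,1.63636363636364,0.04354,-0.00167,0.18491,0.0475,-0.01578,0.22652,1
37,1.68181818181818,0.09288,-0.06667,0.17211,0.04857,-0.02939,0.21131,1
38,1.72727272727273,-0.00906,0.00209,0.17281,-0.00255,-0.03936,0.19586,1
39,1.77272727272727,0.0387,-0.04163,0.18418,0.07721,-0.07776,0.2,1
40,1.81818181818182,0.04132,-0.09293,0.20311,0.02975,-0.11765,0.20376,1
41,1.86363636363636,-0.0115,-0.16236,0.21096,-0.00095,-0.11248,0.19084,1
42,1.90909090909091,-0.03465,-0.18424,0.14088,-0.019,-0.16716,0.15392,1
43,1.95454545454545,-0.04491,-0.12394,0.10564,-0.01286,-0.143,0.13905,1
44,2,0.00056,-0.10224,0.20068,-0.01229,-0.10355,0.18247,1
45,2.04545454545455,-0.04931,-0.09196,0.22696,-0.04409,-0.1024,0.21869,1
46,2.09090909090909,-0.0405,-0.02561,0.25082,-0.05597,-0.0994,0.2161,1
47,2.13636363636364,-0.08669,-0.13264,0.16474,-0.07965,-0.10809,0.21521,1
48,2.18181818181818,-0.10807,-0.13386,0.20333,-0.08832,-0.07047,0.20071,1
49,2.22727272727273,-0.05965,-0.03858,0.20946,-0.09716,-0.04679,0.16886,1
50,2.27272727272727,-0.1022,-0.11108,0.22577,-0.09404,-0.09045,0.20405,1
51,2.31818181818182,-0.06949,-0.08684,0.14174,-0.09793,-0.10022,0.16671,1
52,2.36363636363636,-0.12985,-0.14373,0.1726,-0.09381,-0.11936,0.15063,1
53,2.40909090909091,-0.06566,-0.05287,0.09216,-0.05168,-0.11923,0.11831,1
54,2.45454545454545,-0.05265,-0.12834,0.1225,-0.04457,-0.12463,0.1361,1
55,2.5,-0.01209,-0.16267,0.18544,-0.00037,-0.14835,0.14981,1
56,2.54545454545455,0.04261,-0.12035,0.13418,0.00215,-0.11536,0.14288,1
57,2.59090909090909,0.02604,-0.1358,0.21868,0.02672,-0.16168,0.19382,1
58,2.63636363636364,0.05835,-0.15602,0.1414,0.05103,-0.15894,0.15013,1
59,2.68181818181818,0.03944,-0.1864,0.10265,0.06771,-0.13763,0.14994,1
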