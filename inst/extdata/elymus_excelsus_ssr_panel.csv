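primer_id,class,tnb,npb,ppb,pic,mi,rp,h,i
Cn 159,EST-SSR,8,3,37.50,0.205,0.615,0.72,0.224,0.368
Cn 193,EST-SSR,6,4,66.67,0.179,0.716,0.80,0.429,0.620
Cn 204,EST-SSR,5,2,40,0.355,0.710,1.20,0.428,0.619
Cn 227,EST-SSR,6,3,50,0.169,0.507,0.56,0.200,0.333
Cn 237,EST-SSR,13,9,69.23,0.188,1.692,1.92,0.323,0.483
Cn 278,EST-SSR,6,5,83.33,0.173,0.865,0.96,0.228,0.360
Cn 291,EST-SSR,5,3,60,0.303,0.909,1.12,0.381,0.554
Cn 294,EST-SSR,9,6,66.67,0.384,2.304,3.52,0.345,0.520
Cn 299,EST-SSR,6,3,50,0.226,0.678,0.80,0.339,0.505
Cn 306,EST-SSR,5,2,40,0.147,0.294,0.32,0.406,0.596
Cn 350,EST-SSR,7,5,71.43,0.439,2.195,3.52,0.373,0.554
Cn 362,EST-SSR,5,3,60,0.169,0.507,0.56,0.312,0.470
Cn 479,EST-SSR,6,6,100,0.361,2.166,2.96,0.431,0.611
Cn 48,EST-SSR,4,2,50,0.211,0.422,0.48,0.116,0.232
Elymus 2644,EST-SSR,5,2,40,0.24,0.480,0.56,0.135,0.260
Elymus 3207,EST-SSR,15,13,86.67,0.32,4.160,5.76,0.367,0.543
Elymus 3592,EST-SSR,7,5,71.43,0.279,1.395,1.76,0.279,0.430
Elymus 5264,EST-SSR,16,14,87.50,0.273,3.822,4.96,0.320,0.482
ES 105,EST-SSR,8,5,62.50,0.383,1.915,3.12,0.390,0.570
ES 123,EST-SSR,9,4,44.44,0.238,0.952,1.12,0.380,0.557
ES 176,EST-SSR,4,4,100,0.338,1.352,2.08,0.287,0.440
ES 179,EST-SSR,5,2,40,0.458,0.916,1.44,0.319,0.499
ES 180,EST-SSR,6,3,50,0.382,1.146,1.84,0.337,0.503
ES 261,EST-SSR,5,2,40,0.147,0.294,0.32,0.078,0.171
ES 322,EST-SSR,8,4,50,0.147,0.588,0.64,0.078,0.171
ES 352,EST-SSR,4,4,100,0.226,0.904,1.20,0.221,0.359
ES 51,EST-SSR,9,4,44.44,0.466,1.864,2.96,0.356,0.540
ES 7,EST-SSR,7,1,14.29,0.147,0.147,0.16,0.078,0.171
ES 75,EST-SSR,9,1,11.11,0.461,0.461,0.72,0.480,0.673
ES 82,EST-SSR,5,3,60,0.228,0.684,0.80,0.346,0.519
ESGS 124,G-SSR,5,3,60,0.45,1.35,2.24,0.464,0.657
ESGS 172,G-SSR,8,7,87.50,0.318,2.226,3.12,0.203,0.347
ESGS 266,G-SSR,10,9,90,0.385,3.465,5.28,0.308,0.474
ESGS 292,G-SSR,10,8,80,0.309,2.472,3.60,0.212,0.351
ESGS 52,G-SSR,6,5,83.33,0.404,2.02,3.28,0.365,0.536
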