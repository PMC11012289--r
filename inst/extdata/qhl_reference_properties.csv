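qhl,cluster,ic50_um,pic50_fluor,pic50_abs,pic50_zinc,tsa_delta_c,mw,hba,hbd,tpsa,logd,lipe,qed
1,NA,0.32,6.50,6.06,6.50,6.77,346.40,6,2,95.09,1.65,4.85,0.65
2,26,0.35,6.45,6.10,6.47,3.70,434.91,7,2,104.32,1.56,4.89,0.52
3,26,0.38,6.42,6.15,6.41,5.22,382.47,7,2,108.22,2.34,4.08,0.54
4,NA,0.71,6.15,5.70,6.17,4.00,391.48,6,2,101.08,3.64,2.51,0.48
5,26,1.20,5.92,5.71,5.95,4.29,390.86,6,2,95.09,2.13,3.79,0.59
6,26,1.26,5.90,5.24,5.91,3.55,392.87,6,2,95.09,2.33,3.57,0.57
7,NA,1.29,5.89,<4.70,5.86,0.30,362.80,4,1,33.09,3.79,2.10,0.72
8,26,1.32,5.88,5.45,5.89,4.61,448.94,7,2,104.32,1.94,3.94,0.51
9,1,1.51,5.82,<4.70,5.80,0.15,344.39,7,1,112.49,2.84,2.98,0.79
10,15,1.58,5.80,4.80,5.78,0.30,493.51,9,1,100.65,3.27,2.53,0.46
11,4,1.66,5.78,5.41,5.77,1.92,400.94,5,2,64.15,3.21,2.57,0.83
12,NA,1.91,5.72,4.86,5.71,-0.15,287.75,5,1,55.63,4.04,1.68,0.80
13,NA,2.14,5.67,4.79,5.70,-1.91,392.50,7,0,59.31,3.28,2.39,0.61
14,1,2.24,5.65,<4.70,5.63,0.15,367.46,5,1,86.46,3.23,2.42,0.75
15,10,2.40,5.62,<4.70,5.59,-0.89,363.24,5,0,39.15,2.08,3.54,0.83
16,16,2.63,5.58,5.42,5.55,2.07,368.49,6,2,95.09,2.44,3.14,0.57
17,NA,2.63,5.58,<4.70,5.49,0.30,419.50,7,1,107.82,3.39,2.19,0.70
18,NA,2.82,5.55,5.25,5.57,1.92,485.49,10,1,100.23,2.53,3.02,0.56
19,1,2.82,5.55,4.79,5.53,0.30,355.46,6,2,105.91,3.72,1.83,0.75
20,16,2.82,5.55,5.24,5.5,4.15,404.93,6,2,123.33,2.84,2.71,0.54
21,25,2.95,5.53,5.25,5.55,2.66,330.36,6,2,78.35,2.96,2.57,0.67
22,15,3.09,5.51,<4.70,5.52,0.15,464.52,8,1,95.08,3.17,2.34,0.49
23,NA,3.09,5.51,<4.70,5.49,0.44,250.26,5,0,56.74,2.90,2.61,0.55
24,NA,3.09,5.51,5.52,5.26,4.00,387.47,7,2,98.33,1.94,3.57,0.55
25,1,3.16,5.50,<4.70,5.46,0.00,367.42,6,1,66.81,3.20,2.30,0.77
26,NA,3.24,5.49,5.11,5.45,4.44,428.52,7,2,104.32,2.58,2.91,0.51
27,NA,3.24,5.49,4.97,5.29,1.48,325.40,5,0,59.23,3.35,2.14,0.87
28,NA,3.24,5.49,4.81,5.25,0.15,330.42,4,1,96.50,3.95,1.54,0.73
29,25,3.31,5.48,5.53,5.49,1.92,360.84,6,2,78.35,3.88,1.60,0.64
30,15,3.47,5.46,<4.70,5.41,0.30,464.52,8,1,95.08,3.03,2.43,0.49
31,NA,3.47,5.46,<4.70,5.38,0.00,278.68,2,0,17.82,4.41,1.05,0.64
32,NA,3.47,5.46,<4.70,5.21,0.15,290.36,6,1,59.51,2.36,3.10,0.88
38,4,4.68,5.33,4.96,5.34,2.22,401.93,6,2,77.04,2.27,3.06,0.78
40,10,4.68,5.33,<4.70,5.28,0.30,375.78,7,1,68.25,0.95,4.38,0.85
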