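subject,grade,feature,value,decimals
II-P01,II,FOREHEAD_SD,0.87,2
II-P02,II,FOREHEAD_SD,0.61,2
II-P03,II,FOREHEAD_SD,2.81,2
II-P04,II,FOREHEAD_SD,1.66,2
II-P05,II,FOREHEAD_SD,0.39,2
II-P06,II,FOREHEAD_SD,2.53,2
II-P07,II,FOREHEAD_SD,1.58,2
II-P08,II,FOREHEAD_SD,2.86,2
II-P09,II,FOREHEAD_SD,1.89,2
II-P10,II,FOREHEAD_SD,1.26,2
III-P01,III,FOREHEAD_SD,3.89,2
III-P02,III,FOREHEAD_SD,4.24,2
III-P03,III,FOREHEAD_SD,4,2
III-P04,III,FOREHEAD_SD,3.8,2
III-P05,III,FOREHEAD_SD,3.75,2
III-P06,III,FOREHEAD_SD,3.95,2
III-P07,III,FOREHEAD_SD,3.87,2
III-P08,III,FOREHEAD_SD,4.23,2
III-P09,III,FOREHEAD_SD,4.12,2
III-P10,III,FOREHEAD_SD,4.45,2
IV-P01,IV,FOREHEAD_SD,5.56,2
IV-P02,IV,FOREHEAD_SD,5,2
IV-P03,IV,FOREHEAD_SD,5.23,2
IV-P04,IV,FOREHEAD_SD,4.54,2
IV-P05,IV,FOREHEAD_SD,5.26,2
IV-P06,IV,FOREHEAD_SD,4.82,2
IV-P07,IV,FOREHEAD_SD,5.01,2
IV-P08,IV,FOREHEAD_SD,4.96,2
IV-P09,IV,FOREHEAD_SD,5.78,2
IV-P10,IV,FOREHEAD_SD,5.8,2
V-P01,V,FOREHEAD_SD,6.93,2
V-P02,V,FOREHEAD_SD,11.07,2
V-P03,V,FOREHEAD_SD,6.5,2
V-P04,V,FOREHEAD_SD,6.32,2
V-P05,V,FOREHEAD_SD,6.65,2
V-P06,V,FOREHEAD_SD,7.6,2
V-P07,V,FOREHEAD_SD,10.23,2
V-P08,V,FOREHEAD_SD,8.65,2
V-P09,V,FOREHEAD_SD,9.48,2
V-P10,V,FOREHEAD_SD,8.32,2
II-P01,II,MOUTH_SD,0.93,2
II-P02,II,MOUTH_SD,2.72,2
II-P03,II,MOUTH_SD,2.33,2
II-P04,II,MOUTH_SD,1.65,2
II-P05,II,MOUTH_SD,0.64,2
II-P06,II,MOUTH_SD,0.98,2
II-P07,II,MOUTH_SD,1.33,2
II-P08,II,MOUTH_SD,0.32,2
II-P09,II,MOUTH_SD,0.82,2
II-P10,II,MOUTH_SD,1.73,2
III-P01,III,MOUTH_SD,3,2
III-P02,III,MOUTH_SD,3.13,2
III-P03,III,MOUTH_SD,3.65,2
III-P04,III,MOUTH_SD,3.11,2
III-P05,III,MOUTH_SD,3.31,2
III-P06,III,MOUTH_SD,3.13,2
III-P07,III,MOUTH_SD,3.57,2
III-P08,III,MOUTH_SD,3.9,2
III-P09,III,MOUTH_SD,3.69,2
III-P10,III,MOUTH_SD,3.26,2
IV-P01,IV,MOUTH_SD,4.56,2
IV-P02,IV,MOUTH_SD,3.99,2
IV-P03,IV,MOUTH_SD,4.24,2
IV-P04,IV,MOUTH_SD,4.65,2
IV-P05,IV,MOUTH_SD,3.99,2
IV-P06,IV,MOUTH_SD,4.32,2
IV-P07,IV,MOUTH_SD,4.04,2
IV-P08,IV,MOUTH_SD,4.02,2
IV-P09,IV,MOUTH_SD,4.56,2
IV-P10,IV,MOUTH_SD,4.11,2
V-P01,V,MOUTH_SD,6,2
V-P02,V,MOUTH_SD,5.33,2
V-P03,V,MOUTH_SD,5,2
V-P04,V,MOUTH_SD,5.24,2
V-P05,V,MOUTH_SD,6.13,2
V-P06,V,MOUTH_SD,5.13,2
V-P07,V,MOUTH_SD,4.99,2
V-P08,V,MOUTH_SD,5.55,2
V-P09,V,MOUTH_SD,5.99,2
V-P10,V,MOUTH_SD,6.24,2
II-P01,II,TOTAL_SD,1.8,2
II-P02,II,TOTAL_SD,3.3,1
II-P03,II,TOTAL_SD,5.13,2
II-P04,II,TOTAL_SD,3.31,2
II-P05,II,TOTAL_SD,1.03,2
II-P06,II,TOTAL_SD,3.51,2
II-P07,II,TOTAL_SD,2.91,2
II-P08,II,TOTAL_SD,3.18,2
II-P09,II,TOTAL_SD,2.71,2
II-P10,II,TOTAL_SD,2.98,2
III-P01,III,TOTAL_SD,6.89,2
III-P02,III,TOTAL_SD,7.36,2
III-P03,III,TOTAL_SD,7.65,2
III-P04,III,TOTAL_SD,6.91,2
III-P05,III,TOTAL_SD,7.06,2
III-P06,III,TOTAL_SD,7.08,2
III-P07,III,TOTAL_SD,7.44,2
III-P08,III,TOTAL_SD,8.13,2
III-P09,III,TOTAL_SD,7.81,2
III-P10,III,TOTAL_SD,7.71,2
IV-P01,IV,TOTAL_SD,10.12,2
IV-P02,IV,TOTAL_SD,8.98,2
IV-P03,IV,TOTAL_SD,9.47,2
IV-P04,IV,TOTAL_SD,9.19,2
IV-P05,IV,TOTAL_SD,9.25,2
IV-P06,IV,TOTAL_SD,9.14,2
IV-P07,IV,TOTAL_SD,9.05,2
IV-P08,IV,TOTAL_SD,8.98,2
IV-P09,IV,TOTAL_SD,10.35,2
IV-P10,IV,TOTAL_SD,9.91,2
V-P01,V,TOTAL_SD,12.92,2
V-P02,V,TOTAL_SD,16.39,2
V-P03,V,TOTAL_SD,11.49,2
V-P04,V,TOTAL_SD,11.56,2
V-P05,V,TOTAL_SD,12.78,2
V-P06,V,TOTAL_SD,12.73,2
V-P07,V,TOTAL_SD,15.22,2
V-P08,V,TOTAL_SD,14.2,2
V-P09,V,TOTAL_SD,15.47,2
V-P10,V,TOTAL_SD,14.56,2
II-P01,II,FOREHEAD_AI,0.8,2
II-P02,II,FOREHEAD_AI,0.85,2
II-P03,II,FOREHEAD_AI,0.98,2
II-P04,II,FOREHEAD_AI,0.98,2
II-P05,II,FOREHEAD_AI,0.78,2
II-P06,II,FOREHEAD_AI,0.92,2
II-P07,II,FOREHEAD_AI,0.78,2
II-P08,II,FOREHEAD_AI,0.74,2
II-P09,II,FOREHEAD_AI,0.76,2
II-P10,II,FOREHEAD_AI,0.93,2
III-P01,III,FOREHEAD_AI,0.55,2
III-P02,III,FOREHEAD_AI,0.68,2
III-P03,III,FOREHEAD_AI,0.63,2
III-P04,III,FOREHEAD_AI,0.65,2
III-P05,III,FOREHEAD_AI,0.59,2
III-P06,III,FOREHEAD_AI,0.68,2
III-P07,III,FOREHEAD_AI,0.54,2
III-P08,III,FOREHEAD_AI,0.58,2
III-P09,III,FOREHEAD_AI,0.58,2
III-P10,III,FOREHEAD_AI,0.64,2
IV-P01,IV,FOREHEAD_AI,0.52,2
IV-P02,IV,FOREHEAD_AI,0.5,2
IV-P03,IV,FOREHEAD_AI,0.5,2
IV-P04,IV,FOREHEAD_AI,0.43,2
IV-P05,IV,FOREHEAD_AI,0.47,2
IV-P06,IV,FOREHEAD_AI,0.41,2
IV-P07,IV,FOREHEAD_AI,0.47,2
IV-P08,IV,FOREHEAD_AI,0.44,2
IV-P09,IV,FOREHEAD_AI,0.48,2
IV-P10,IV,FOREHEAD_AI,0.45,2
V-P01,V,FOREHEAD_AI,0.03,2
V-P02,V,FOREHEAD_AI,0.26,2
V-P03,V,FOREHEAD_AI,0.16,2
V-P04,V,FOREHEAD_AI,0.12,2
V-P05,V,FOREHEAD_AI,0.29,2
V-P06,V,FOREHEAD_AI,0.18,2
V-P07,V,FOREHEAD_AI,0.38,2
V-P08,V,FOREHEAD_AI,0.33,2
V-P09,V,FOREHEAD_AI,0.32,2
V-P10,V,FOREHEAD_AI,0.17,2
II-P01,II,MOUTH_AI,0.84,2
II-P02,II,MOUTH_AI,0.8,2
II-P03,II,MOUTH_AI,0.77,2
II-P04,II,MOUTH_AI,0.76,2
II-P05,II,MOUTH_AI,0.73,2
II-P06,II,MOUTH_AI,0.94,2
II-P07,II,MOUTH_AI,0.91,2
II-P08,II,MOUTH_AI,0.78,2
II-P09,II,MOUTH_AI,0.84,2
II-P10,II,MOUTH_AI,0.91,2
III-P01,III,MOUTH_AI,0.64,2
III-P02,III,MOUTH_AI,0.61,2
III-P03,III,MOUTH_AI,0.6,2
III-P04,III,MOUTH_AI,0.61,2
III-P05,III,MOUTH_AI,0.65,2
III-P06,III,MOUTH_AI,0.65,2
III-P07,III,MOUTH_AI,0.69,2
III-P08,III,MOUTH_AI,0.55,2
III-P09,III,MOUTH_AI,0.55,2
III-P10,III,MOUTH_AI,0.68,2
IV-P01,IV,MOUTH_AI,0.5,2
IV-P02,IV,MOUTH_AI,0.48,2
IV-P03,IV,MOUTH_AI,0.48,2
IV-P04,IV,MOUTH_AI,0.45,2
IV-P05,IV,MOUTH_AI,0.5,2
IV-P06,IV,MOUTH_AI,0.51,2
IV-P07,IV,MOUTH_AI,0.51,2
IV-P08,IV,MOUTH_AI,0.5,2
IV-P09,IV,MOUTH_AI,0.43,2
IV-P10,IV,MOUTH_AI,0.45,2
V-P01,V,MOUTH_AI,0.14,2
V-P02,V,MOUTH_AI,0.22,2
V-P03,V,MOUTH_AI,0.25,2
V-P04,V,MOUTH_AI,0.14,2
V-P05,V,MOUTH_AI,0.28,2
V-P06,V,MOUTH_AI,0.28,2
V-P07,V,MOUTH_AI,0.34,2
V-P08,V,MOUTH_AI,0.1,2
V-P09,V,MOUTH_AI,0.33,2
V-P10,V,MOUTH_AI,0.33,2
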