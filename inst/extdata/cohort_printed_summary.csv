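feature,grade,stat,printed,audited
FOREHEAD_SD,II,mean,1.65,TRUE
FOREHEAD_SD,II,max,2.86,TRUE
FOREHEAD_SD,II,min,0.4,FALSE
FOREHEAD_SD,II,sd,0.89,TRUE
FOREHEAD_SD,III,mean,4.03,TRUE
FOREHEAD_SD,III,max,4.46,FALSE
FOREHEAD_SD,III,min,3.76,FALSE
FOREHEAD_SD,III,sd,0.23,FALSE
FOREHEAD_SD,IV,mean,5.2,TRUE
FOREHEAD_SD,IV,max,5.81,FALSE
FOREHEAD_SD,IV,min,4.54,TRUE
FOREHEAD_SD,IV,sd,0.42,FALSE
FOREHEAD_SD,V,mean,8.18,TRUE
FOREHEAD_SD,V,max,11.07,TRUE
FOREHEAD_SD,V,min,6.33,FALSE
FOREHEAD_SD,V,sd,1.67,TRUE
MOUTH_SD,II,mean,1.34,FALSE
MOUTH_SD,II,max,2.72,TRUE
MOUTH_SD,II,min,0.32,TRUE
MOUTH_SD,II,sd,0.76,TRUE
MOUTH_SD,III,mean,3.37,FALSE
MOUTH_SD,III,max,3.9,TRUE
MOUTH_SD,III,min,3,TRUE
MOUTH_SD,III,sd,0.3,TRUE
MOUTH_SD,IV,mean,4.25,TRUE
MOUTH_SD,IV,max,4.65,TRUE
MOUTH_SD,IV,min,3.99,TRUE
MOUTH_SD,IV,sd,0.26,TRUE
MOUTH_SD,V,mean,5.56,TRUE
MOUTH_SD,V,max,6.24,TRUE
MOUTH_SD,V,min,4.99,TRUE
MOUTH_SD,V,sd,0.48,FALSE
TOTAL_SD,II,mean,2.99,TRUE
TOTAL_SD,II,max,5.13,TRUE
TOTAL_SD,II,min,1.03,TRUE
TOTAL_SD,II,sd,1.07,FALSE
TOTAL_SD,III,mean,7.4,TRUE
TOTAL_SD,III,max,8.13,TRUE
TOTAL_SD,III,min,6.89,TRUE
TOTAL_SD,III,sd,0.41,FALSE
TOTAL_SD,IV,mean,9.44,TRUE
TOTAL_SD,IV,max,10.35,TRUE
TOTAL_SD,IV,min,8.98,TRUE
TOTAL_SD,IV,sd,0.5,TRUE
TOTAL_SD,V,mean,13.73,TRUE
TOTAL_SD,V,max,16.39,TRUE
TOTAL_SD,V,min,11.49,TRUE
TOTAL_SD,V,sd,1.68,TRUE
FOREHEAD_AI,II,mean,0.85,TRUE
FOREHEAD_AI,II,max,0.98,TRUE
FOREHEAD_AI,II,min,0.74,TRUE
FOREHEAD_AI,II,sd,0.09,TRUE
FOREHEAD_AI,III,mean,0.61,TRUE
FOREHEAD_AI,III,max,0.68,TRUE
FOREHEAD_AI,III,min,0.54,TRUE
FOREHEAD_AI,III,sd,0.05,TRUE
FOREHEAD_AI,IV,mean,0.46,FALSE
FOREHEAD_AI,IV,max,0.52,TRUE
FOREHEAD_AI,IV,min,0.41,TRUE
FOREHEAD_AI,IV,sd,0.03,TRUE
FOREHEAD_AI,V,mean,0.22,TRUE
FOREHEAD_AI,V,max,0.38,TRUE
FOREHEAD_AI,V,min,0.03,TRUE
FOREHEAD_AI,V,sd,0.1,FALSE
MOUTH_AI,II,mean,0.82,FALSE
MOUTH_AI,II,max,0.94,TRUE
MOUTH_AI,II,min,0.73,TRUE
MOUTH_AI,II,sd,0.07,TRUE
MOUTH_AI,III,mean,0.62,TRUE
MOUTH_AI,III,max,0.69,TRUE
MOUTH_AI,III,min,0.55,TRUE
MOUTH_AI,III,sd,0.04,FALSE
MOUTH_AI,IV,mean,0.48,TRUE
MOUTH_AI,IV,max,0.51,TRUE
MOUTH_AI,IV,min,0.43,TRUE
MOUTH_AI,IV,sd,0.02,FALSE
MOUTH_AI,V,mean,0.24,TRUE
MOUTH_AI,V,max,0.34,TRUE
MOUTH_AI,V,min,0.1,TRUE
MOUTH_AI,V,sd,0.08,FALSE
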