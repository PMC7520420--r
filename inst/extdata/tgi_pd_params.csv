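agent,model,model_type,doses_mg_per_kg,kgEx,cv_kgEx,kg,cv_kg,Vmax,cv_Vmax,tau,cv_tau,kkmax,cv_kkmax,kc50,cv_kc50,n,cv_n,psi,omega_kgEx,omega_kg,additive_error,proportional_error
PF-06804103,JIMT-1,CLX,0;0.25;0.5;1,0.0883,8,47.5,23,4080,15,2.23,6,0.703,9,10.6,9,2.4,12,20,0.401,1.23,13.4,0.118
PF-06804103,N87,CLX,0;0.3;1;3,0.068,8,26.8,14,4600,20,2.54,6,0.15,5,1.24,16,1,NA,20,0.271,0.666,34.9,0.055
PF-06804103,BT474,CLX,0;0.5;1.5,0.0442,65,78.5,23,5280,23,3.04,16,0.998,209,31.5,236,1,NA,20,2.59,0.717,106,NA
PF-06804103,24312,PDX,0;1.5;3;6,0.023,12,24.4,15,5000,NA,1.66,1,0.721,0,15.8,5,2.6,NA,20,0.373,0.0441,19.1,0.227
PF-06804103,37622,PDX,0;0.3;1;3,0.0559,9,68.4,22,3840,13,3.32,5,0.362,13,4.19,19,1.3,7,20,0.372,0.789,35.8,0.0755
PF-06804103,144580,PDX,0;1.5;3;6,0.0461,8,395,65,5920,16,9,5,0.516,13,25.8,16,2.4,21,20,0.359,1.3,63.4,0.0648
PF-06804103,GA-3109,PDX,0;1;3,0.115,6,57.2,9,7070,26,5.81,2,1.24,2,14.7,6,2.5,6,20,0.25,0.316,18.3,0.188
T-DM1,N87,CLX,0;1;3;10,0.0732,11,37.9,17,4220,18,1.36,16,0.405,38,131,48,1,NA,20,0.47,0.781,66.8,0.0727
T-DM1,BT474,CLX,0;1;3;10,0.0575,46,77.4,20,5280,23,2.4,7,1.38,91,311,110,1.01,4,20,2.26,0.917,30,0.157
T-DM1,HCC-1954,CLX,0;0.3;1;3,0.0918,8,40.7,6,3180,27,1,8,0.319,7,8.63,10,1.5,NA,20,0.371,0.274,14.4,0.0754
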