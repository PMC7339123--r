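compound,dphi_b_max,k_uM,dphi_d_max,delta_t_p,neg_delta_t_m,delta_t_half,rf_max
caffeine,2,na,na,0,0,0,3
pentoxifylline,4,na,na,0,0,0,2
dimethylxanthine_1_7,23,11,21,0,0,0,5
dimethylxanthine_3_9,4,na,na,0,0,0,4
theophylline,41,42,40,na,0.2,0.1,6
isobutylmethylxanthine,22,33,20,na,0.9,0.1,7
etofylline,6,na,na,0,0,0,4
lupinine,3,na,na,0,0.5,0.1,5
cotinine,6,na,na,0,0,0,3
atropine,4,na,na,0,0,0,3
quinine,26,80,16,na,0.6,0.7,12
berberine,3,na,na,na,0.3,0.1,12
piperine,51,79,40,na,2.9,0.9,31
melatonin,26,37,15,na,0.7,0.1,2
tabersonine,6,na,na,na,0.2,2.4,81
colchicine,27,19,29,2.5,0.8,0.9,4
capsaicin,118,32,92,na,4.8,3.6,57
dihydrocapsaicin,119,26,92,na,4.1,2.2,66
hordenine,29,19,23,3.0,1.0,0.1,6
synephrine,41,44,24,3.2,0.8,0.1,6
solanidine,2,na,na,na,0.9,1.1,4
conessine,19,29,12,na,1.8,0.7,30
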