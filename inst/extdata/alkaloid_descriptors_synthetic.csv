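compound,logd,dipole_moment
caffeine,-0.07,3.7
pentoxifylline,0.29,4.4
dimethylxanthine_1_7,-0.37,4.0
dimethylxanthine_3_9,-0.70,4.5
theophylline,-0.05,3.9
isobutylmethylxanthine,0.95,4.1
etofylline,-0.65,4.8
lupinine,-1.00,2.1
cotinine,0.07,4.3
atropine,-0.20,3.1
quinine,2.20,2.9
berberine,-1.30,2.4
piperine,3.00,3.6
melatonin,1.40,4.0
tabersonine,1.00,2.6
colchicine,1.03,5.9
capsaicin,3.75,3.8
dihydrocapsaicin,3.95,3.9
hordenine,-0.90,2.0
synephrine,-2.20,2.8
solanidine,5.40,1.9
conessine,2.00,1.2
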