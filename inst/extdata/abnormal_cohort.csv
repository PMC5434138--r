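id,crl_ga,valve_est,valve_error,fhr_est,fhr_error,fhr_bpm,dus_sqi,fecg_sqi,abnormality
1,33,35,2,32,-1,202,0.8,0.5,Tachycardia
2,35,32,-3,29,-6,175,0.8,0.5,Tachycardia
3,38,33,-5,48,10,133,0.8,0.4,Arrhythmia
4,37,42,5,47,10,105,0.5,0.3,Bradycardia for SSS
5,38,41,3,76,38,104,0.6,0.3,Bradycardia for SSS
6,35,46,11,34,-1,138,0.8,0.4,WPW
7,37,37,0,118,81,117,0.9,0.3,PAC
8,32,36,4,33,1,142,0.7,0.4,Loss of FHRV-distress
9,30,36,6,33,3,149,0.4,0.4,Heart failure
10,33,33,0,34,1,132,0.1,0.5,Heart anomaly
11,36,33,-3,33,-3,145,0.9,0.5,Heart anomaly
12,30,32,2,35,5,135,0.3,0.3,Heart anomaly
13,34,35,1,30,-4,152,0.5,0.5,Heart anomaly
14,22,36,14,41,19,133,0.6,0.2,Heart anomaly
15,22,38,16,54,32,122,0.6,0.3,Heart anomaly
16,36,32,-4,34,-2,144,0.9,0.3,Heart anomaly
17,28,29,1,32,4,147,0.7,0.3,TOF
18,28,30,2,43,15,145,0.5,0.3,TOF-VSD-PA-MS-PAC
19,23,70,47,63,40,67,0.5,0.2,VSD-ASD-CDH-CA
20,35,80,45,104,69,65,0.7,0.2,AV block
21,27,96,69,87,60,68,0.7,0.2,AV block-SA-CAV
22,24,82,58,86,62,62,0.6,0.3,PA-CAVC-SA-AV block-PS
23,26,35,9,37,11,127,0.3,0.3,Ebstein's anomaly
24,33,39,6,57,24,122,0.6,0.3,Cardiac dilatation-CHD
25,20,67,47,89,69,78,0.3,0.2,NIHF
26,29,35,6,33,4,144,0.9,0.3,NIHF-Hydrops amnii
27,18,25,7,29,11,158,0.8,0.4,TTTS Donner
28,35,36,1,31,-4,152,0.3,0.5,Acute crisis-placental abruption
29,24,32,8,31,7,147,0.9,0.3,Placental dysfunction
30,31,20,-11,30,-1,163,0.6,0.3,History of intrauterine death
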