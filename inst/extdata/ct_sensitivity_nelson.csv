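stage,histology,all_screen_average,baseline,repeat,nlst
IA,adenocarcinoma,59.4,41.0,70.9,56.6
IB,adenocarcinoma,67.5,49.0,77.1,64.1
II,adenocarcinoma,73.7,56.3,81.9,64.5
IIIA,adenocarcinoma,99.3,99.3,99.3,75.9
IIIB,adenocarcinoma,99.7,99.5,99.8,80.2
IV,adenocarcinoma,100.0,99.9,100.0,98.9
IA,squamous,30.1,30.1,30.1,31.0
IB,squamous,30.4,30.4,30.4,38.0
II,squamous,79.3,79.3,79.3,39.2
IIIA,squamous,96.7,96.7,96.7,69.7
IIIB,squamous,99.3,99.3,99.3,79.4
IV,squamous,99.9,99.9,99.9,97.7
IA,other_nsclc,24.6,24.6,24.6,20.8
IB,other_nsclc,26.4,26.4,26.4,24.8
II,other_nsclc,39.6,39.6,39.6,24.8
IIIA,other_nsclc,67.5,67.5,67.5,60.4
IIIB,other_nsclc,89.8,89.8,89.8,68.3
IV,other_nsclc,99.2,99.2,99.2,95.7
IA,sclc,8.8,8.8,8.8,8.8
IB,sclc,10.3,10.3,10.3,10.3
II,sclc,11.2,11.2,11.2,11.2
IIIA,sclc,78.7,78.7,78.7,41.6
IIIB,sclc,96.8,96.8,96.8,87.1
IV,sclc,99.9,99.9,99.9,99.4
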