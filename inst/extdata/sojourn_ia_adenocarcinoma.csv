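trial,stage,histology,sex,mean,shape
NELSON,IA,adenocarcinoma,male,3.56,0.35
NELSON,IA,adenocarcinoma,female,4.77,0.35
NLST,IA,adenocarcinoma,male,1.82,1.44
NLST,IA,adenocarcinoma,female,2.43,1.44
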