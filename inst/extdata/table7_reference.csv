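marker_id,priming_dose_mSv,challenge_dose_mSv,rared_mSv,rarf
GSH,5,50,9.7,0.91
CAT,5,50,5.6,0.99
SOD,5,50,7.4,0.96
MDA,5,50,6.1,0.98
EPR,5,50,19.4,0.92
TM,5,50,9.4,0.92
DNA,5,50,9.6,0.92
TL,5,50,9.6,0.92
OTM,5,50,13.1,0.85
Hb,5,50,16.6,0.79
RDW,5,50,14.6,0.83
GSH,10,50,19.9,0.84
CAT,10,50,16.5,0.89
SOD,10,50,23.6,0.77
MDA,10,50,16.6,0.89
EPR,10,50,32.6,0.62
TM,10,50,18.8,0.85
DNA,10,50,22.8,0.79
TL,10,50,17.9,0.87
OTM,10,50,23.8,0.77
Hb,10,50,40.9,0.49
RDW,10,50,20.6,0.82
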