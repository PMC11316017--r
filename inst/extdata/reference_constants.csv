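marker_id,family,p1,p2,p3,se1,se2,se3,r_value,goodness,units
GSH,exponential,88.43,-0.085,14.8,26.17,0.062,15.78,0.962,Fit converged,mg/dL
CAT,exponential,0.00605,-0.054,0.0888,0.00075,0.018,0.00077,0.995,Fit converged,U/L
SOD,linear,-0.0022,0.6365,,0.000178,0.00576,,-0.994,0.006,U/mL
MDA,quadratic,31.93,8.15,-0.103,13.49,3.7,0.0741,0.9331,0.258,nmol/mL
EPR,linear,0.153,45,,0.003,0.114,,0.9996,4.03e-4,a.u.
CA,exponential,-14.04,-0.112,21.18,1.803,0.0297,1.589,0.9996,Fit converged,%
TM,exponential,-1.342,-0.067,2.506,0.016,0.002,0.015,0.9999,Fit converged,um
DNA,linear,0.149,9.852,,0.0045,0.131,,0.991,8.9e-4,%
TL,quadratic,6.136,0.1886,-0.0019,0.0724,0.0167,0.000326,0.9992,0.0402,um
OTM,exponential,-1.211,-0.0214,1.741,0.556,0.0128,0.564,0.993,Fit converged,um
Hb,linear,-0.0115,14.78,,0.0012,0.039,,-0.979,0.011,g/dL
MCV,exponential,-9.73,-0.095,101.4,1.05,0.02,1.035,0.997,Fit converged,fL
RDW,linear,0.141,28.43,,0.0117,0.215,,0.9931,0.007,%
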