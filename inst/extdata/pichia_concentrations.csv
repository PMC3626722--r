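metabolite,mean,sd,n
Glc6P,2.6,0.26,6
Fru6P,0.57,0.06,6
FBP,1.3,0.13,6
DHAP,0.34,0.04,6
GA3P,0.035,0.004,6
PG3,0.85,0.09,6
PG2,0.155,0.016,6
PEP,0.51,0.05,6
Xul5P,0.07,0.008,6
Rib5P,0.14,0.015,6
Sed7P,0.55,0.06,6
E4P,0.04,0.005,6
Fum,0.59,0.06,6
Mal,2.2,0.22,6
Man6P,0.21,0.02,6
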