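metabolite,pool
Glc6P,2.6
Fru6P,0.57
FBP,1.3
DHAP,0.34
GA3P,0.035
PG3,0.85
PG2,0.155
PEP,0.51
PyrC,0.45
P6G,0.16
Rul5P,0.10
Xul5P,0.07
Rib5P,0.14
Sed7P,0.55
E4P,0.04
MetOH,0.60
Cit,4.8
AKG,0.95
Suc,1.1
Fum,0.59
Mal,2.2
Glu,18.0
Asp,7.5
Ala,10.5
Tre,16.0
G1P,0.32
Man6P,0.21
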