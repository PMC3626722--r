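# Cofactor production coefficients per reaction of the shipped network
# (mol cofactor per mol flux; consumption negative). Lumped steps carry the
# sum of their elementary reactions (emp6 = GAPDH+PGK, tca4 = AKGDH + SucCoA
# synthetase). The PDH-bypass aldehyde dehydrogenase is taken as
# NADP-dependent, the classical cytosolic route in yeast.
po_ratio: 1.48
growth_atp: 5.9
NADH:
  emp6: 1
  tca1: 1
  tca3: 1
  tca4.a: 1
  tca4.b: 1
  tca7: 1
  met2: 1
  met3: 1
NADPH:
  ppp1: 1
  ppp2: 1
  ana2: 1
  ald1: 1
FADH2:
  tca5.a: 1
  tca5.b: 1
ATP:
  upt1: -1
  emp2: -1
  emp6: 1
  emp10: 1
  emp12: -2
  ana1: -1
  sto2: -1
  met5: -1
  tca4.a: 1
  tca4.b: 1
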