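# Thermodynamic model of the cytosolic central-carbon reactions used for NET
# analysis. Transformed standard reaction Gibbs energies (kJ/mol) at ionic
# strength 0.15 M; values are representative group-contribution-scale
# estimates shipped as inputs (the package does not compute them). Reactions
# releasing or consuming protons carry per-pH entries so that the pH
# dependence of cofactor-ratio bounds can be explored (scenarios 7.0, 7.2,
# 7.5). Water and protons are excluded from the stoichiometries; their
# activity is absorbed in drg0.
temperature: 298.15
ph: 7.2
ionic_strength: 0.15
cell_volume: 1.7
reactions:
  pgi:
    stoich: {Glc6P: -1, Fru6P: 1}
    drg0: 2.5
  pmi:
    stoich: {Fru6P: -1, Man6P: 1}
    drg0: -0.5
  fba:
    stoich: {FBP: -1, DHAP: 1, GA3P: 1}
    drg0: 19.8
  tpi:
    stoich: {DHAP: -1, GA3P: 1}
    drg0: 5.3
  pgm:
    stoich: {PG3: -1, PG2: 1}
    drg0: 4.0
  eno:
    stoich: {PG2: -1, PEP: 1}
    drg0: -4.1
  tkt1:
    stoich: {Xul5P: -1, Rib5P: -1, Sed7P: 1, GA3P: 1}
    drg0: -3.8
  tal:
    stoich: {Sed7P: -1, GA3P: -1, E4P: 1, Fru6P: 1}
    drg0: -0.7
  tkt2:
    stoich: {Xul5P: -1, E4P: -1, Fru6P: 1, GA3P: 1}
    drg0: -10.0
  fmh:
    stoich: {Fum: -1, Mal: 1}
    drg0: -3.4
  mdh:
    stoich: {Mal: -1, NAD: -1, OAA: 1, NADH: 1}
    drg0: {"7.0": 28.6, "7.2": 27.5, "7.5": 25.8}
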