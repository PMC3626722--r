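# Flux constraints for the reduced P. pastoris glucose-methanol network.
# Units: mmol/gCDW/h. Glucose and methanol uptake are the measured chemostat
# rates; the nine biomass precursor drains follow from the biomass
# macromolecular composition and the dilution rate (0.09 1/h); the unlabeled
# mitochondrial pyruvate source and sink are tied so that carbon balance is
# preserved. CO2 excretion is left unconstrained: with both uptakes and all
# drains fixed it is implied by carbon conservation and becomes a model
# prediction. The four symmetric-product reaction pairs (tca4, tca5 fwd/bwd,
# tca6, tca8) carry structural 1:1 ties inside the network definition itself.
fixed:
  upt1: 0.71
  upt2: 0.94
  bm_glc6p: 0.130
  bm_man6p: 0.040
  bm_rib5p: 0.045
  bm_e4p: 0.030
  bm_pg3: 0.060
  bm_ala: 0.060
  bm_glu: 0.105
  bm_asp: 0.080
  bm_accoa: 0.285
ties:
  - emp11C == emp11D
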