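# Measured fragment set for the reduced P. pastoris network. A stand-in for
# the study's LC-/GC-MS fragment list: it covers the metabolites whose
# labeling dynamics the study displays (upper glycolysis, PPP, methanol
# assimilation products, TCA intermediates, amino-acid buffers, trehalose).
# Positions are 1-based carbon numbers; glucose-6-phosphate is detected via
# its C3-C6 fragment.
glc6p_c3c6: {metabolite: Glc6P, positions: 3-6, formula: C6H12O9P}
fru6p: {metabolite: Fru6P, positions: 1-6, formula: C6H12O9P}
fbp: {metabolite: FBP, positions: 1-6, formula: C6H13O12P2}
dhap: {metabolite: DHAP, positions: 1-3, formula: C3H6O6P}
ga3p: {metabolite: GA3P, positions: 1-3, formula: C3H6O6P}
pg3: {metabolite: PG3, positions: 1-3, formula: C3H6O7P}
pep: {metabolite: PEP, positions: 1-3, formula: C3H4O6P}
pyr: {metabolite: PyrC, positions: 1-3, formula: C3H3O3}
xul5p: {metabolite: Xul5P, positions: 1-5, formula: C5H10O8P}
rib5p: {metabolite: Rib5P, positions: 1-5, formula: C5H10O8P}
sed7p: {metabolite: Sed7P, positions: 1-7, formula: C7H14O10P}
e4p: {metabolite: E4P, positions: 1-4, formula: C4H8O7P}
dha: {metabolite: DHA, positions: 1-3, formula: C3H6O3}
cit: {metabolite: Cit, positions: 1-6, formula: C6H7O7}
akg: {metabolite: AKG, positions: 1-5, formula: C5H5O5}
suc: {metabolite: Suc, positions: 1-4, formula: C4H5O4}
fum: {metabolite: Fum, positions: 1-4, formula: C4H3O4}
mal: {metabolite: Mal, positions: 1-4, formula: C4H5O5}
glu: {metabolite: Glu, positions: 1-5, formula: C5H8NO4}
asp: {metabolite: Asp, positions: 1-4, formula: C4H6NO4}
ala: {metabolite: Ala, positions: 1-3, formula: C3H6NO2}
tre_half: {metabolite: Tre, positions: 1-6, formula: C6H11O6}
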