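# Reduced atom-transition network for P. pastoris co-assimilating glucose and
# methanol in a carbon-limited chemostat. Reconstructed from the pathway
# content named in the study it emulates: glycolysis/gluconeogenesis with
# FBPase, oxidative + non-oxidative pentose phosphate pathway, methanol
# dissimilation (MetOH -> Form -> FOR -> CO2) and assimilation (DAS),
# trehalose cycling, PDH bypass, TCA cycle with Asp lyase, anaplerosis,
# alpha-ketoglutarate/Glu and OAA/Asp exchanges, an unlabeled mitochondrial
# pyruvate source/sink pair, and biomass precursor drains. Cytosol and
# peroxisome are lumped; pyruvate is split into cytosolic and mitochondrial
# pools. 37 balanced metabolites; 79 reactions counting bidirectional fluxes
# and both members of each symmetric-product pair.

@boundary: Glc.ext MeOH.ext CO2.ext Pyr.unl.ext Pyr.sink.ext
@boundary: BM.Glc6P BM.Man6P BM.Rib5P BM.E4P BM.PG3 BM.Ala BM.Glu BM.Asp BM.ACCoA

# uptake and excretion
upt1: Glc.ext(abcdef) -> Glc6P(abcdef)
upt2: MeOH.ext(a) -> MetOH(a)
co2out: CO2(a) -> CO2.ext(a)

# biomass precursor drains (rates fixed from biomass composition x growth rate)
bm_glc6p: Glc6P(abcdef) -> BM.Glc6P(abcdef)
bm_man6p: Man6P(abcdef) -> BM.Man6P(abcdef)
bm_rib5p: Rib5P(abcde) -> BM.Rib5P(abcde)
bm_e4p: E4P(abcd) -> BM.E4P(abcd)
bm_pg3: PG3(abc) -> BM.PG3(abc)
bm_ala: Ala(abc) -> BM.Ala(abc)
bm_glu: Glu(abcde) -> BM.Glu(abcde)
bm_asp: Asp(abcd) -> BM.Asp(abcd)
bm_accoa: ACCoAm(ab) -> BM.ACCoA(ab)

# glycolysis / gluconeogenesis
emp1: Glc6P(abcdef) <-> Fru6P(abcdef)
emp2: Fru6P(abcdef) -> FBP(abcdef)
emp3: FBP(abcdef) -> Fru6P(abcdef)
emp4: FBP(abcdef) <-> DHAP(abc) + GA3P(def)
emp5: DHAP(abc) <-> GA3P(cba)
emp6: GA3P(abc) <-> PG3(abc)
emp7: PG3(abc) -> PG2(abc)
emp8: PG2(abc) <-> PEP(abc)
emp10: PEP(abc) -> PyrC(abc)
pyrT: PyrC(abc) -> PyrM(abc)

# PDH bypass (pyruvate decarboxylase, aldehyde dehydrogenase, ACS, transport)
emp9: PyrC(abc) -> AcAld(bc) + CO2(a)
ald1: AcAld(ab) -> Ace(ab)
emp12: Ace(ab) -> ACCoAc(ab)
acT: ACCoAc(ab) -> ACCoAm(ab)

# unlabeled mitochondrial pyruvate source and sink (tied 1:1 in constraints)
emp11C: Pyr.unl.ext(abc) -> PyrM(abc)
emp11D: PyrM(abc) -> Pyr.sink.ext(abc)

# pentose phosphate pathway
ppp1: Glc6P(abcdef) -> P6G(abcdef)
ppp2: P6G(abcdef) -> Rul5P(bcdef) + CO2(a)
ppp3: Rul5P(abcde) <-> Xul5P(abcde)
ppp4: Rul5P(abcde) <-> Rib5P(abcde)
ppp5: Xul5P(abcde) + Rib5P(fghij) <-> Sed7P(abfghij) + GA3P(cde)
ppp6: Sed7P(abcdefg) + GA3P(hij) <-> E4P(defg) + Fru6P(abchij)
ppp7: Xul5P(abcde) + E4P(fghi) <-> Fru6P(abfghi) + GA3P(cde)

# methanol dissimilation and assimilation
met1: MetOH(a) -> Form(a)
met2: Form(a) -> FOR(a)
met3: FOR(a) -> CO2(a)
met4: Form(a) + Xul5P(bcdef) -> DHA(bca) + GA3P(def)
met5: DHA(abc) -> DHAP(abc)

# TCA cycle (succinate and fumarate formations carry two 1:1 atom maps)
tca1: PyrM(abc) -> ACCoAm(bc) + CO2(a)
tca2: ACCoAm(ab) + OAA(cdef) -> Cit(fedbac)
tca3: Cit(abcdef) -> AKG(abcde) + CO2(f)
tca4: AKG(abcde) -> Suc(bcde) + CO2(a) | Suc(edcb) + CO2(a)
tca5: Suc(abcd) <-> Fum(abcd) | Fum(dcba)
tca6: Fum(abcd) <-> Mal(abcd) | Mal(dcba)
tca7: Mal(abcd) <-> OAA(abcd)
tca8: Asp(abcd) -> Fum(abcd) | Fum(dcba)

# anaplerosis and malic enzyme
ana1: PyrC(abc) + CO2(d) -> OAA(abcd)
ana2: Mal(abcd) -> PyrM(abc) + CO2(d)

# amino-acid exchange pools
aa_ala: PyrC(abc) <-> Ala(abc)
aa_glu: AKG(abcde) <-> Glu(abcde)
aa_asp: OAA(abcd) <-> Asp(abcd)

# trehalose cycling and mannose drain precursor
sto1: Glc6P(abcdef) -> G1P(abcdef)
sto2: G1P(abcdef) + Glc6P(ghijkl) -> Tre(abcdefghijkl)
sto3: Tre(abcdefghijkl) -> Glc6P(abcdef) + Glc6P(ghijkl)
man1: Fru6P(abcdef) -> Man6P(abcdef)
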