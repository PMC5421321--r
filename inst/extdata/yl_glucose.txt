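# Yarrowia lipolytica central-carbon network, glucose mono-substrate mode.
# One reaction per line: "id: A + B -> C + D | abc + d -> abcd | rev|irr".
# Compartments are encoded as metabolite suffixes: .c cytosol, .m mitochondrion,
# .e extracellular.  Atom strings are 1-based from the carboxyl/aldehyde carbon.
input: GLC.e
symmetric: SUC.m FUM.m
unbalanced: BIOMASS.c LIPID.c
glc_upt: GLC.e -> G6P.c | abcdef -> abcdef | irr
pgi: G6P.c -> F6P.c | abcdef -> abcdef | rev
pfk: F6P.c -> FBP.c | abcdef -> abcdef | rev
fba: FBP.c -> DHAP.c + GAP.c | abcdef -> cba + def | rev
tpi: DHAP.c -> GAP.c | abc -> abc | rev
gapdh: GAP.c -> PGA.c | abc -> abc | rev
eno: PGA.c -> PEP.c | abc -> abc | rev
pyk: PEP.c -> PYR.c | abc -> abc | irr
g6pdh: G6P.c -> RU5P.c + CO2.c | abcdef -> bcdef + a | irr
rpi: RU5P.c -> R5P.c | abcde -> abcde | rev
rpe: RU5P.c -> X5P.c | abcde -> abcde | rev
tkt1: X5P.c + R5P.c -> S7P.c + GAP.c | abcde + fghij -> abfghij + cde | rev
tal: S7P.c + GAP.c -> F6P.c + E4P.c | abcdefg + hij -> abchij + defg | rev
tkt2: X5P.c + E4P.c -> F6P.c + GAP.c | abcde + fghi -> abfghi + cde | rev
pyrt: PYR.c -> PYR.m | abc -> abc | irr
pdh: PYR.m -> ACA.m + CO2.c | abc -> bc + a | irr
cs: ACA.m + OAA.m -> CIT.m | ab + cdef -> fedbac | irr
idh: CIT.m -> AKG.m + CO2.c | abcdef -> abcde + f | irr
akgdh: AKG.m -> SUC.m + CO2.c | abcde -> bcde + a | irr
sdh: SUC.m -> FUM.m | abcd -> abcd | irr
fum: FUM.m -> MAL.m | abcd -> abcd | rev
mdh_m: MAL.m -> OAA.m | abcd -> abcd | rev
pc: PYR.c + CO2.c -> OAA.c | abc + d -> abcd | irr
citexp: CIT.m -> CIT.c | abcdef -> abcdef | irr
dic: MAL.c -> MAL.m | abcd -> abcd | irr
acl: CIT.c -> ACA.c + OAA.c | abcdef -> ed + fcba | irr
mdh_c: OAA.c -> MAL.c | abcd -> abcd | irr
citsec: CIT.c -> CIT.e | abcdef -> abcdef | irr
lip: ACA.c -> LIPID.c | ab -> ab | irr
co2_out: CO2.c -> CO2.e | a -> a | irr
bm: 1.07 G6P.c + 0.59 R5P.c + 0.36 E4P.c + 0.13 GAP.c + 1.5 PGA.c + 0.65 PEP.c + 2.26 PYR.c + 1.5 ACA.c + 1.79 OAA.c + 1.34 AKG.m -> 1 BIOMASS.c | - | irr
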