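# Free-text reagent spellings mapped to canonical names. Keys are matched
# after case-folding and whitespace collapsing; edit freely.
sodium dithionite: Na2S2O4
sodium hydrosulfite: Na2S2O4
sodium sulfite: Na2SO3
thiourea dioxide: TDO
lithium aluminium hydride: LiAlH4
lithium aluminum hydride: LiAlH4
sodium borohydride: NaBH4
diisobutylaluminium hydride: DIBAL-H
diisobutylaluminum hydride: DIBAL-H
hydrogen peroxide: H2O2
peracetic acid: AcOOH
meta-chloroperoxybenzoic acid: mCPBA
sodium hydroxide: NaOH
caustic soda: NaOH
potassium hydroxide: KOH
sodium bicarbonate: NaHCO3
sodium carbonate: Na2CO3
sodium ethoxide: NaOEt
sodium methoxide: NaOMe
potassium tert-butoxide: KOtBu
hydrochloric acid: HCl
sulfuric acid: H2SO4
hydrobromic acid: HBr
acetic acid: AcOH
sodium nitrite: NaNO2
benzylamine: BnNH2
triethylamine: Et3N
raney nickel: Raney Ni
palladium on carbon: Pd/C
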