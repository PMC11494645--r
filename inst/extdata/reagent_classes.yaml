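# Reagent/condition taxonomy: 21 classes. Each class has a priority (lower
# matches first: reductants, oxidants and organometallics take precedence
# over acids and bases) and a synonym list compared after case-folding and
# the reagent_synonyms.yaml mapping. The class names reconstruct the field's
# usual groupings; membership is configuration and can be edited.
- name: S-based reductant
  priority: 1
  synonyms: [na2s2o4, na2so3, tdo, sodium dithionite, sodium sulfite, thiourea dioxide]
- name: hydride reductant
  priority: 2
  synonyms: [lialh4, nabh4, dibal-h, dibal, libh4, nabh3cn, red-al]
- name: dissolving metal
  priority: 3
  synonyms: [zn, zinc, fe, iron, sn, tin, zn/hcl, zn/acoh, na/hg]
- name: peroxide oxidant
  priority: 4
  synonyms: [h2o2, acooh, mcpba, tbhp, oxone, peracetic acid]
- name: Grignard
  priority: 5
  synonyms: [etmgbr, memgbr, phmgbr, memgcl, grignard reagent]
- name: alkyllithium
  priority: 6
  synonyms: [n-buli, nbuli, buli, meli, s-buli, t-buli, phli]
- name: H2/heterogeneous catalyst
  priority: 7
  synonyms: [h2, hydrogen, pd/c, 10% pd/c, 5% pd/c, raney ni, pt/c, pd(oh)2]
- name: transition-metal catalyst
  priority: 8
  synonyms: [pd(oac)2, pd(pph3)4, cucl, cui, cu(oac)2, fecl3, rucl3, nicl2]
- name: nitrosating agent
  priority: 9
  synonyms: [nano2, nobf4, isoamyl nitrite, t-buono, noCl, nitrosylsulfuric acid]
- name: stabilized carbanion
  priority: 10
  synonyms: [diethyl malonate, dimethyl malonate, ethyl acetoacetate, malononitrile]
- name: N-nucleophile
  priority: 11
  synonyms: [bnnh2, morpholine, piperidine, dimethylamine, diethylamine, aniline, hydrazine, nh3, ammonia]
- name: arene
  priority: 12
  synonyms: [benzene, toluene, anisole, phenol, mesitylene]
- name: halide source
  priority: 13
  synonyms: [nacl, kbr, ki, nai, licl, nbu4ni]
- name: strong mineral acid
  priority: 14
  synonyms: [hcl, h2so4, hbr, hi, hno3, hclo4]
- name: dilute acid
  priority: 15
  synonyms: [acoh, formic acid, citric acid, dilute hcl, nh4cl]
- name: alkoxide base
  priority: 16
  synonyms: [naoet, naome, kotbu, naotbu, lioet]
- name: strong base
  priority: 17
  synonyms: [naoh, koh, lioh, csoh, dbu, nah]
- name: mild base
  priority: 18
  synonyms: [nahco3, na2co3, k2co3, cs2co3, et3n, pyridine, 2,6-lutidine]
- name: photochemical
  priority: 19
  synonyms: [hv, light, uv, photolysis]
- name: thermal only
  priority: 20
  synonyms: [heat, thermal, reflux, neat]
- name: unclassified
  priority: 21
  synonyms: []
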