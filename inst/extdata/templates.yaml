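# Transformation-template metadata for the synthetic dataset generator.
# The structural rewrite of each template is implemented in code and looked
# up by name; this file carries the editable metadata: the transformation
# label the template realises, the reagents/conditions recorded with
# generated records (chosen to be consistent with the stated reagent
# class), and the substrate classes the template applies to.
# aryl_free_slot: the non-defining substituent must be drawn from the aryl
# vocabulary (Fischer-Hepp needs an N-aryl ring to migrate into).
- name: denitrosation
  transformation: reduction to amine/denitrosation
  reagent_class: S-based reductant
  reagent_names: [Na2S2O4, NaOH]
  solvents: [water]
  temperature_c: 50
  applicable_classes: [dialkyl, alkyl-aryl, diaryl, alkyl-carbamate, alkyl-amide, alkyl-urea]
  aryl_free_slot: false
- name: hydrazine_reduction
  transformation: reduction to hydrazine
  reagent_class: hydride reductant
  reagent_names: [LiAlH4]
  solvents: [THF]
  temperature_c: 25
  applicable_classes: [dialkyl, alkyl-aryl, diaryl, alkyl-carbamate, alkyl-amide, alkyl-urea]
  aryl_free_slot: false
- name: diazonium_formation
  transformation: diazonium formation
  reagent_class: strong base
  reagent_names: [NaOH]
  solvents: [water]
  temperature_c: 25
  applicable_classes: [alkyl-aryl, diaryl, alkyl-carbamate, alkyl-amide, alkyl-urea]
  aryl_free_slot: false
- name: fischer_hepp
  transformation: Fischer-Hepp rearrangement
  reagent_class: strong mineral acid
  reagent_names: [HCl]
  solvents: [ethanol]
  temperature_c: 25
  applicable_classes: [alkyl-aryl, diaryl, alkyl-carbamate, alkyl-amide, alkyl-urea]
  aryl_free_slot: true
- name: transnitrosation
  transformation: transnitrosation
  reagent_class: N-nucleophile
  reagent_names: [morpholine]
  solvents: [water]
  temperature_c: 80
  applicable_classes: [dialkyl, alkyl-aryl, diaryl, alkyl-carbamate, alkyl-amide, alkyl-urea]
  aryl_free_slot: false
- name: nitramine_oxidation
  transformation: oxidation to N-nitramine
  reagent_class: peroxide oxidant
  reagent_names: [H2O2]
  solvents: [water]
  temperature_c: 25
  applicable_classes: [dialkyl, alkyl-aryl, diaryl, alkyl-carbamate, alkyl-amide, alkyl-urea]
  aryl_free_slot: false
- name: spectator_esterification
  transformation: spectator
  reagent_class: mild base
  reagent_names: [Et3N]
  solvents: [DCM]
  temperature_c: 0
  applicable_classes: [dialkyl, alkyl-aryl]
  aryl_free_slot: false
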