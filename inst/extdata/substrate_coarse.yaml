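# Mapping of fine substrate labels to coarse classes C1-C8. The coarse
# grouping is configuration, not chemistry: edit to regroup classes.
dialkyl: C1
alkyl-aryl: C2
diaryl: C3
alkyl-amide: C4
alkyl-carbamate: C5
alkyl-urea: C6
alkyl-guanidine: C7
alkyl-sulfonyl: C8
other: unassigned
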