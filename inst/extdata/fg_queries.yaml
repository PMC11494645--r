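# Functional-group queries: {name, smarts} entries in the package's SMARTS
# subset. The default query matches N-N=O on a trisubstituted amine nitrogen.
- name: N-nitrosamine
  smarts: "[#7;X3]([!#1])([!#1])[#7]=[#8]"
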