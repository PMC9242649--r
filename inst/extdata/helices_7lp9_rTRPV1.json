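{
  "_comment": "Approximate transmembrane helix ranges for rat TRPV1 (PDB 7LP9, author residue numbering), from the published TRPV1 architecture; verify against the deposited entry before quantitative use.",
  "TM1": [433, 460],
  "TM2": [467, 491],
  "TM3": [504, 530],
  "TM4": [535, 556],
  "TM5": [572, 597],
  "TM6": [629, 661]
}
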