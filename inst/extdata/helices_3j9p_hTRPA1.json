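{
  "_comment": "Approximate transmembrane helix ranges for human TRPA1 (PDB 3J9P, author residue numbering), from the published TRPA1 architecture; verify against the deposited entry before quantitative use.",
  "TM1": [718, 744],
  "TM2": [751, 778],
  "TM3": [784, 807],
  "TM4": [812, 834],
  "TM5": [847, 874],
  "TM6": [935, 960]
}
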