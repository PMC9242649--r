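[
  {"label": "W", "allowed": ["W"], "align_col": 81, "rtrpv1_pos": 426},
  {"label": "F", "allowed": ["F"], "align_col": 320, "rtrpv1_pos": 434},
  {"label": "Φ", "allowed": ["F", "Y"], "align_col": 331, "rtrpv1_pos": 441},
  {"label": "G", "allowed": ["G"], "align_col": 633, "rtrpv1_pos": 563},
  {"label": "Φ", "allowed": ["F", "Y"], "align_col": 662, "rtrpv1_pos": 591},
  {"label": "Φ", "allowed": ["F", "Y"], "align_col": 755, "rtrpv1_pos": 638},
  {"label": "Φ", "allowed": ["F", "Y"], "align_col": 852, "rtrpv1_pos": 666},
  {"label": "N", "allowed": ["N"], "align_col": 862, "rtrpv1_pos": 676},
  {"label": "L", "allowed": ["L"], "align_col": 864, "rtrpv1_pos": 678},
  {"label": "I", "allowed": ["I"], "align_col": 865, "rtrpv1_pos": 679},
  {"label": "A", "allowed": ["A"], "align_col": 866, "rtrpv1_pos": 680},
  {"label": "W", "allowed": ["W"], "align_col": 883, "rtrpv1_pos": 697}
]
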