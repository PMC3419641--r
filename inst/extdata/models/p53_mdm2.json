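{
  "comment": "Four-variable logical model of the p53-Mdm2 damage-response network. P = p53 (levels 0-2), Mc = cytoplasmic Mdm2, Mn = nuclear Mdm2, dam = DNA damage. Nuclear Mdm2 represses p53; p53 drives cytoplasmic Mdm2, which drives nuclear import; basal nuclear entry of Mdm2 requires absence of p53 and of damage; damage decays with its degradation propensity (repair) and has no activator.",
  "variables": [
    {"name": "P", "levels": 3},
    {"name": "Mc", "levels": 2},
    {"name": "Mn", "levels": 2},
    {"name": "dam", "levels": 2}
  ],
  "rules": {
    "P": "2 * (Mn == 0)",
    "Mc": "P >= 1",
    "Mn": "max(Mc, min(P == 0, dam == 0))",
    "dam": "0"
  },
  "propensities": {
    "P": {"up": 0.9, "down": 0.9},
    "Mc": {"up": 0.9, "down": 0.9},
    "Mn": {"up": 0.9, "down": 0.9},
    "dam": {"up": 1, "down": 0.05}
  }
}
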