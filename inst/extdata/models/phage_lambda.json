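{
  "comment": "Core lysis/lysogeny switch of phage lambda after the Thieffry-Thomas logical model. CI (levels 0-2) is fully expressed when CRO is absent or CII is present, and fully repressed when CRO is active with CII absent; CRO (levels 0-3) is repressed by fully expressed CI and represses itself at its top level (2-cycle 0200/0300 = lysis); CII needs N and is repressed by CI and by CRO >= 2; N is repressed by CI and by CRO >= 2. Default propensities are the CI-favouring set.",
  "variables": [
    {"name": "CI", "levels": 3},
    {"name": "CRO", "levels": 4},
    {"name": "CII", "levels": 2},
    {"name": "N", "levels": 2}
  ],
  "rules": {
    "CI": "2 * max(CRO == 0, CII)",
    "CRO": "(CI < 2) * (2 + (CRO < 3))",
    "CII": "min(N, CI == 0, CRO <= 1)",
    "N": "min(CI == 0, CRO <= 1)"
  },
  "propensities": {
    "CI": {"up": 0.8, "down": 0.2},
    "CRO": {"up": 0.2, "down": 0.8},
    "CII": {"up": 0.9, "down": 0.9},
    "N": {"up": 0.9, "down": 0.9}
  }
}
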