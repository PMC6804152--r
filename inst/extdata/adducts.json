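[
  {
    "name": "[M-H]-",
    "polarity": "negative",
    "delta": -1.007276452161,
    "charge": 1
  },
  {
    "name": "[M+HCOO]-",
    "polarity": "negative",
    "delta": 44.998202851179,
    "charge": 1
  },
  {
    "name": "[M+CH3COO]-",
    "polarity": "negative",
    "delta": 59.013852915319,
    "charge": 1
  },
  {
    "name": "[M+Cl]-",
    "polarity": "negative",
    "delta": 34.969401259909,
    "charge": 1
  },
  {
    "name": "[M+e]-",
    "polarity": "negative",
    "delta": 0.000548579909,
    "charge": 1
  },
  {
    "name": "[M+H]+",
    "polarity": "positive",
    "delta": 1.007276452161,
    "charge": 1
  },
  {
    "name": "[M+Na]+",
    "polarity": "positive",
    "delta": 22.989220700991,
    "charge": 1
  },
  {
    "name": "[M-e]+",
    "polarity": "positive",
    "delta": -0.000548579909,
    "charge": 1
  }
]
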