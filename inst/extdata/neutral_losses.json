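[
  {
    "name": "Glc",
    "formula": "C6H10O5",
    "mass": 162.0528234187,
    "role": "sugar"
  },
  {
    "name": "Rha",
    "formula": "C6H10O4",
    "mass": 146.0579087991,
    "role": "sugar"
  },
  {
    "name": "GlurA",
    "formula": "C6H8O6",
    "mass": 176.03208797416,
    "role": "sugar"
  },
  {
    "name": "Pen",
    "formula": "C5H8O4",
    "mass": 132.04225873496,
    "role": "sugar"
  },
  {
    "name": "malonyl",
    "formula": "C3H2O3",
    "mass": 86.00039392294,
    "role": "acyl"
  },
  {
    "name": "acetyl",
    "formula": "C2H2O",
    "mass": 42.01056468374,
    "role": "acyl"
  },
  {
    "name": "H2O",
    "formula": "H2O",
    "mass": 18.01056468374,
    "role": "small"
  },
  {
    "name": "CO2",
    "formula": "CO2",
    "mass": 43.9898292392,
    "role": "small"
  },
  {
    "name": "CO",
    "formula": "CO",
    "mass": 27.9949146196,
    "role": "small"
  },
  {
    "name": "HCOOH",
    "formula": "CH2O2",
    "mass": 46.00547930334,
    "role": "small"
  },
  {
    "name": "CH4",
    "formula": "CH4",
    "mass": 16.03130012828,
    "role": "small"
  },
  {
    "name": "CH3OH",
    "formula": "CH4O",
    "mass": 32.02621474788,
    "role": "small"
  },
  {
    "name": "CH3",
    "formula": "CH3",
    "mass": 15.02347509621,
    "role": "small"
  },
  {
    "name": "C6H12",
    "formula": "C6H12",
    "mass": 84.09390038484,
    "role": "side-chain"
  },
  {
    "name": "danshensu",
    "formula": "C9H10O5",
    "mass": 198.0528234187,
    "role": "acid-unit"
  },
  {
    "name": "caffeoyl",
    "formula": "C9H8O4",
    "mass": 180.04225873496,
    "role": "acid-unit"
  },
  {
    "name": "feruloyl",
    "formula": "C10H8O3",
    "mass": 176.04734411536,
    "role": "acid-unit"
  }
]
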