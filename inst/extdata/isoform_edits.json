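[
  {"taxon": "Neanderthal", "protein": "COL4A5", "from": 1264, "to": 1270,
   "action": "delete",
   "note": "isoform interval absent from the archaic references (P29400 coordinates)"},
  {"taxon": "Chimp", "protein": "COL4A5", "from": 1264, "to": 1270,
   "action": "delete",
   "note": "same interval removed for the chimpanzee reference"},
  {"taxon": "Gorilla", "protein": "COL11A1", "from": 261, "to": 313,
   "action": "delete",
   "note": "COL11A1 isoform interval removed for all individuals (P12107 coordinates)"},
  {"taxon": "Gorilla", "protein": "COL18A1", "from": 220, "to": 454,
   "action": "insert_unknowns",
   "note": "235 unknowns after position 219 (P39060 coordinates): missing reference portion"},
  {"taxon": "Gorilla", "protein": "COL27A1", "from": 3, "to": 21,
   "action": "mask",
   "note": "major sequence differences replaced by unknowns (Q8IZC6 coordinates)"}
]
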