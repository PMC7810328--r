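{
  "d": 3,
  "N": 2,
  "E": 0,
  "mode": "2D",
  "alphabet": ["A", "C", "G", "T"],
  "positions": {
    "A": [5, 8],
    "C": [7, 5],
    "G": [8, 4],
    "T": [5, 4]
  },
  "score": 0
}
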