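{
  "d": 3,
  "N": 2,
  "E": 0,
  "mode": "2D",
  "alphabet": ["A", "C", "G", "T"],
  "positions": {
    "A": [1, 4],
    "C": [6, 9],
    "G": [5, 3],
    "T": [2, 8]
  },
  "score": 928
}
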