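{
  "d": 3,
  "N": 3,
  "E": 0,
  "mode": "2D",
  "alphabet": ["A", "C", "G", "T"],
  "positions": {
    "A": [3, 7, 9],
    "C": [7, 6, 9],
    "G": [6, 8, 3],
    "T": [8, 9, 4]
  },
  "score": 0
}
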