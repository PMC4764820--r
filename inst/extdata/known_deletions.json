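{
  "b2/b3":   {"deleted": ["sY1191"],           "retained": ["sY1192", "sY1291", "sY1189"]},
  "gr/gr":   {"deleted": ["sY1291"],           "retained": ["sY1191", "sY1192"]},
  "b1/b3":   {"deleted": ["sY1191", "sY1192"], "retained": ["sY1291", "sY1189"]},
  "b1/b2":   {"deleted": ["sY1192"],           "retained": ["sY1191", "sY1291", "sY1189"]},
  "DAZ-loss": {"deleted": ["sY1189"],          "retained": ["sY1192"]}
}
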