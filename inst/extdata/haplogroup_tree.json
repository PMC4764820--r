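[
  {"name": "Y",    "parent": null, "markers": []},
  {"name": "J",    "parent": "Y",   "markers": [{"marker": "MK_J",    "ancestral": "A", "derived": "G"}]},
  {"name": "T",    "parent": "Y",   "markers": [{"marker": "MK_T",    "ancestral": "C", "derived": "T"}]},
  {"name": "N",    "parent": "Y",   "markers": [{"marker": "MK_N",    "ancestral": "G", "derived": "A"}]},
  {"name": "Q",    "parent": "Y",   "markers": [{"marker": "MK_Q",    "ancestral": "C", "derived": "G"}]},
  {"name": "C",    "parent": "Y",   "markers": [{"marker": "MK_C",    "ancestral": "T", "derived": "C"}]},
  {"name": "D",    "parent": "Y",   "markers": [{"marker": "MK_D",    "ancestral": "A", "derived": "C"}]},
  {"name": "R",    "parent": "Y",   "markers": [{"marker": "MK_R",    "ancestral": "G", "derived": "T"}]},
  {"name": "G",    "parent": "Y",   "markers": [{"marker": "MK_G",    "ancestral": "T", "derived": "A"}]},
  {"name": "O",    "parent": "Y",   "markers": [{"marker": "MK_O",    "ancestral": "A", "derived": "C"}]},
  {"name": "O3a",  "parent": "O",   "markers": [{"marker": "MK_O3A",  "ancestral": "G", "derived": "C"}]},
  {"name": "O1a2", "parent": "O",   "markers": [{"marker": "MK_O1A2", "ancestral": "T", "derived": "G"}]},
  {"name": "O2*",  "parent": "O",   "markers": [{"marker": "MK_O2",   "ancestral": "C", "derived": "A"}]},
  {"name": "O2a",  "parent": "O2*", "markers": [{"marker": "MK_O2A",  "ancestral": "A", "derived": "T"}]},
  {"name": "O2b",  "parent": "O2*", "markers": [{"marker": "MK_O2B",  "ancestral": "G", "derived": "A"}]}
]
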