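{
  "schema_version": 1,
  "layout_id": "deap32",
  "regions": [
    { "name": "Pre-frontal",       "electrodes": ["FP1", "FP2", "AF3", "AF4"] },
    { "name": "Frontal",           "electrodes": ["F3", "FZ", "F4"] },
    { "name": "Bilateral frontal", "electrodes": ["F7", "F8"] },
    { "name": "Left temporal",     "electrodes": ["FC5", "T7", "CP5"] },
    { "name": "Right temporal",    "electrodes": ["FC6", "T8", "CP6"] },
    { "name": "Frontal central",   "electrodes": ["FC1", "FC2"] },
    { "name": "Central",           "electrodes": ["C3", "CZ", "C4"] },
    { "name": "Central parietal",  "electrodes": ["CP1", "CP2"] },
    { "name": "Bilateral parietal","electrodes": ["P7", "P8"] },
    { "name": "Parietal",          "electrodes": ["P3", "PZ", "P4"] },
    { "name": "Parietal occipital","electrodes": ["PO3", "PO4"] },
    { "name": "Occipital",         "electrodes": ["O1", "OZ", "O2"] }
  ]
}
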