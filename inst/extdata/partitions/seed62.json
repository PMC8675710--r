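{
  "schema_version": 1,
  "layout_id": "seed62",
  "regions": [
    { "name": "Pre-frontal",       "electrodes": ["AF3", "FP1", "FPZ", "FP2", "AF4"] },
    { "name": "Frontal",           "electrodes": ["F3", "F1", "FZ", "F2", "F4"] },
    { "name": "Bilateral frontal", "electrodes": ["F7", "F5", "F6", "F8"] },
    { "name": "Left temporal",     "electrodes": ["FT7", "FC5", "T7", "C5", "TP7", "CP5"] },
    { "name": "Right temporal",    "electrodes": ["FT8", "FC6", "T8", "C6", "TP8", "CP6"] },
    { "name": "Frontal central",   "electrodes": ["FC3", "FC1", "FCZ", "FC2", "FC4"] },
    { "name": "Central",           "electrodes": ["C3", "C1", "CZ", "C2", "C4"] },
    { "name": "Central parietal",  "electrodes": ["CP3", "CP1", "CPZ", "CP2", "CP4"] },
    { "name": "Bilateral parietal","electrodes": ["P7", "P5", "P6", "P8"] },
    { "name": "Parietal",          "electrodes": ["P3", "P1", "PZ", "P2", "P4"] },
    { "name": "Parietal occipital","electrodes": ["PO5", "PO3", "POZ", "PO4", "PO6"] },
    { "name": "Occipital",         "electrodes": ["CB1", "O1", "OZ", "O2", "CB2"] }
  ]
}
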