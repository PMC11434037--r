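{
  "_comment": [
    "Default immunophenoscore configuration. Determinant names and weights",
    "follow the published IPS scheme: +1 for determinants positive to the",
    "immune response (each MHC molecule, ICOS, CD27, acCD4, acCD8, TemCD4,",
    "TemCD8), -1 for determinants negative to it (PD-1, CTLA4, LAG3, TIGIT,",
    "TIM3, PD-L1, PD-L2, Tregs, MDSCs). Entries with listed_in_source=false",
    "(the MHC membership, IDO1, and all metagene gene lists) are defaults",
    "taken from the original IPS publication's scheme and are meant to be",
    "overridden with a study-specific configuration."
  ],
  "categories": {
    "effector_cells": [
      {"name": "acCD4", "weight": 1, "listed_in_source": false,
       "genes": ["CD40LG", "IL2", "CD69", "ICOS"]},
      {"name": "acCD8", "weight": 1, "listed_in_source": false,
       "genes": ["CD8A", "GZMA", "GZMB", "IFNG"]},
      {"name": "TemCD4", "weight": 1, "listed_in_source": false,
       "genes": ["IL7R", "CD44", "CCR4"]},
      {"name": "TemCD8", "weight": 1, "listed_in_source": false,
       "genes": ["EOMES", "GZMK", "KLRG1"]}
    ],
    "suppressor_cells": [
      {"name": "Tregs", "weight": -1, "listed_in_source": false,
       "genes": ["FOXP3", "IL2RA", "IKZF2"]},
      {"name": "MDSCs", "weight": -1, "listed_in_source": false,
       "genes": ["CD14", "ITGAM", "S100A8", "S100A9"]}
    ],
    "mhc": [
      {"name": "B2M", "weight": 1, "listed_in_source": false, "genes": ["B2M"]},
      {"name": "HLA-A", "weight": 1, "listed_in_source": false, "genes": ["HLA-A"]},
      {"name": "HLA-B", "weight": 1, "listed_in_source": false, "genes": ["HLA-B"]},
      {"name": "HLA-C", "weight": 1, "listed_in_source": false, "genes": ["HLA-C"]},
      {"name": "HLA-DPA1", "weight": 1, "listed_in_source": false, "genes": ["HLA-DPA1"]},
      {"name": "HLA-DPB1", "weight": 1, "listed_in_source": false, "genes": ["HLA-DPB1"]},
      {"name": "HLA-E", "weight": 1, "listed_in_source": false, "genes": ["HLA-E"]},
      {"name": "HLA-F", "weight": 1, "listed_in_source": false, "genes": ["HLA-F"]},
      {"name": "TAP1", "weight": 1, "listed_in_source": false, "genes": ["TAP1"]},
      {"name": "TAP2", "weight": 1, "listed_in_source": false, "genes": ["TAP2"]}
    ],
    "checkpoints": [
      {"name": "ICOS", "weight": 1, "listed_in_source": true, "genes": ["ICOS"]},
      {"name": "CD27", "weight": 1, "listed_in_source": true, "genes": ["CD27"]},
      {"name": "PD-1", "weight": -1, "listed_in_source": true, "genes": ["PDCD1"]},
      {"name": "CTLA4", "weight": -1, "listed_in_source": true, "genes": ["CTLA4"]},
      {"name": "LAG3", "weight": -1, "listed_in_source": true, "genes": ["LAG3"]},
      {"name": "TIGIT", "weight": -1, "listed_in_source": true, "genes": ["TIGIT"]},
      {"name": "TIM3", "weight": -1, "listed_in_source": true, "genes": ["HAVCR2"]},
      {"name": "PD-L1", "weight": -1, "listed_in_source": true, "genes": ["CD274"]},
      {"name": "PD-L2", "weight": -1, "listed_in_source": true, "genes": ["PDCD1LG2"]},
      {"name": "IDO1", "weight": 1, "listed_in_source": false, "genes": ["IDO1"]}
    ]
  }
}
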