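{
  "table5": {
    "description": "Solubility classification of 278 marketed drugs via the dose-number rule; rows true {high, low}, columns predicted {high, low}",
    "task": "solubility",
    "counts": [[113, 45], [17, 103]]
  },
  "table6": {
    "description": "Permeability classification of 222 marketed drugs, basis logP; rows true {high, low}, columns predicted {high, low}",
    "task": "permeability_logP",
    "counts": [[99, 45], [19, 59]]
  },
  "table7": {
    "description": "Permeability classification of 222 marketed drugs, basis logD; rows true {high, low}, columns predicted {high, low}",
    "task": "permeability_logD",
    "counts": [[123, 21], [40, 38]]
  },
  "table8": {
    "description": "Permeability classification of 222 marketed drugs, basis logPapp; rows true {high, low}, columns predicted {high, low}",
    "task": "permeability_logPapp",
    "counts": [[105, 39], [20, 58]]
  },
  "table10": {
    "description": "BCS 4-class prediction on 206 marketed drugs; rows predicted class 1-4, columns true class 1-4",
    "task": "bcs_class",
    "orientation": "predicted_rows_true_cols",
    "counts": [[33, 8, 12, 0], [19, 39, 3, 1], [11, 2, 31, 7], [3, 17, 10, 10]]
  },
  "table9_printed_cutoffs": {
    "description": "Cutoffs as printed in the jejunal-permeability table header",
    "logP": 1.72,
    "logD": -0.195,
    "logPapp": -5.097
  }
}
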