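{
  "logP_cutoff": 1.72,
  "logD_cutoff": -0.1954,
  "logPapp_cutoff": -5.097,
  "usp_solubility_cutoff": 0.1,
  "D0_boundary": 1
}
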