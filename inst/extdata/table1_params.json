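{
  "3pc_iv": {
    "model": "3pc",
    "kPL": 0.5, "kLP": 0.02, "kecP": 0.03, "kecL": 0.03, "kve": 0.011,
    "vb": 0.15, "vee": 0.425, "vc": 0.425, "vif_scale": 1.0
  },
  "3pc_ee": {
    "model": "3pc",
    "kPL": 0.5, "kLP": 0.02, "kecP": 0.03, "kecL": 0.03, "kve": 0.066,
    "vb": 0.1, "vee": 0.45, "vc": 0.45, "vif_scale": 1.0
  },
  "3pc_c": {
    "model": "3pc",
    "kPL": 0.2, "kLP": 0.0008, "kecP": 0.2, "kecL": 0.2, "kve": 0.08,
    "vb": 0.02, "vee": 0.196, "vc": 0.784, "vif_scale": 1.0
  },
  "3pcs_iv": {
    "model": "3pcs",
    "kPL": 0.5645, "kecP": 0.0253, "kve": 0.0113, "betaL": 0.0095,
    "vb": 0.15, "vee": 0.425, "vc": 0.425, "vif_scale": 1.0
  },
  "3pcs_ee": {
    "model": "3pcs",
    "kPL": 0.5371, "kecP": 0.0293, "kve": 0.0566, "betaL": 0.0393,
    "vb": 0.1, "vee": 0.45, "vc": 0.45, "vif_scale": 1.0
  },
  "3pcs_c": {
    "model": "3pcs",
    "kPL": 0.2061, "kecP": 0.1211, "kve": 0.1656, "betaL": 0.078,
    "vb": 0.02, "vee": 0.196, "vc": 0.784, "vif_scale": 1.0
  }
}
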