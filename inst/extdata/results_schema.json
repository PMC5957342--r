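{
  "title": "densassign pipeline result",
  "required": [
    "package_version",
    "seed",
    "config_hash",
    "site",
    "lifetimes",
    "relative",
    "absolute_water",
    "verdict"
  ],
  "properties": {
    "package_version": {"type": "string"},
    "seed": {"type": "integer"},
    "config_hash": {"type": "string"},
    "site": {"type": "string"},
    "lifetimes": {
      "properties": {
        "water": {"required": ["tau_ns", "lower_bound"]},
        "ion": {"required": ["tau_ns", "lower_bound"]}
      }
    },
    "relative": {"required": ["ddg", "stderr"]},
    "absolute_water": {"required": ["delta_g", "stderr"]},
    "verdict": {"required": ["call", "rationale", "evidence"]}
  }
}
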