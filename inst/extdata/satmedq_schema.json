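{
  "name": "SATMED-Q",
  "items": ["te1", "te2", "te3", "conv1", "conv2", "conv3", "idl1", "idl2", "idl3", "mc1", "mc2", "use1", "use2", "use3", "gs1", "gs2", "gs3"],
  "response_min": 0,
  "response_max": 4,
  "domains": {
    "treatment_effectiveness": ["te1", "te2", "te3"],
    "convenience_of_use": ["conv1", "conv2", "conv3"],
    "impact_daily_living": ["idl1", "idl2", "idl3"],
    "medical_care": ["mc1", "mc2"],
    "undesirable_side_effects": ["use1", "use2", "use3"],
    "general_satisfaction": ["gs1", "gs2", "gs3"]
  },
  "reverse_items": ["use1", "use2", "use3"],
  "total_rule": "sum_of_items"
}
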