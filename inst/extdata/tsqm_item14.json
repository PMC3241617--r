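{
  "name": "TSQM item #14",
  "column": "anchor",
  "response_min": 1,
  "response_max": 7,
  "neutral": 4,
  "labels": ["extremely dissatisfied", "very dissatisfied", "dissatisfied", "neither satisfied nor dissatisfied", "satisfied", "very satisfied", "extremely satisfied"]
}
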