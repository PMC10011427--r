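[
  {"name": "AQ", "kind": "numeric", "levels": null, "weight": 1},
  {"name": "WS", "kind": "numeric", "levels": null, "weight": 1},
  {"name": "HM", "kind": "numeric", "levels": null, "weight": 1},
  {"name": "WM", "kind": "numeric", "levels": null, "weight": 1}
]
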