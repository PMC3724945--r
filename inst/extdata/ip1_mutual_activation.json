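{
  "nodes": ["n1", "n2"],
  "edges": [
    [
      "n1",
      "n1",
      1
    ],
    [
      "n2",
      "n1",
      1
    ],
    [
      "n2",
      "n2",
      1
    ],
    [
      "n1",
      "n2",
      1
    ]
  ],
  "rule": "MR",
  "tie_prob": {
    "n1": "1/2",
    "n2": "1/2"
  }
}
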