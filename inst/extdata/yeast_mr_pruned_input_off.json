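{
  "nodes": ["Cln3", "MBF", "SBF", "Cln1_2", "Cdh1", "Swi5", "Cdc20", "Clb5_6", "Sic1", "Clb1_2", "Mcm1_SFF"],
  "edges": [
    [
      "Cln3",
      "MBF",
      1
    ],
    [
      "Cln3",
      "SBF",
      1
    ],
    [
      "SBF",
      "Cln1_2",
      1
    ],
    [
      "MBF",
      "Clb5_6",
      1
    ],
    [
      "Clb5_6",
      "Mcm1_SFF",
      1
    ],
    [
      "Clb5_6",
      "Clb1_2",
      1
    ],
    [
      "Clb1_2",
      "Mcm1_SFF",
      1
    ],
    [
      "Clb1_2",
      "Cdc20",
      1
    ],
    [
      "Mcm1_SFF",
      "Clb1_2",
      1
    ],
    [
      "Mcm1_SFF",
      "Cdc20",
      1
    ],
    [
      "Mcm1_SFF",
      "Swi5",
      1
    ],
    [
      "Cdc20",
      "Swi5",
      1
    ],
    [
      "Cdc20",
      "Sic1",
      1
    ],
    [
      "Cdc20",
      "Cdh1",
      1
    ],
    [
      "Swi5",
      "Sic1",
      1
    ],
    [
      "Cln1_2",
      "Sic1",
      -1
    ],
    [
      "Cln1_2",
      "Cdh1",
      -1
    ],
    [
      "Clb5_6",
      "Sic1",
      -1
    ],
    [
      "Clb5_6",
      "Cdh1",
      -1
    ],
    [
      "Clb1_2",
      "Sic1",
      -1
    ],
    [
      "Clb1_2",
      "Cdh1",
      -1
    ],
    [
      "Clb1_2",
      "Swi5",
      -1
    ],
    [
      "Clb1_2",
      "MBF",
      -1
    ],
    [
      "Clb1_2",
      "SBF",
      -1
    ],
    [
      "Sic1",
      "Clb5_6",
      -1
    ],
    [
      "Sic1",
      "Clb1_2",
      -1
    ],
    [
      "Cdh1",
      "Clb1_2",
      -1
    ],
    [
      "Cdc20",
      "Clb5_6",
      -1
    ],
    [
      "Cdc20",
      "Clb1_2",
      -1
    ]
  ],
  "rule": "MR",
  "tie_prob": {
    "Cln3": "1/2",
    "MBF": "1/2",
    "SBF": "1/2",
    "Cln1_2": "1/2",
    "Cdh1": "1/2",
    "Swi5": "1/2",
    "Cdc20": "1/2",
    "Clb5_6": "1/2",
    "Sic1": "1/2",
    "Clb1_2": "1/2",
    "Mcm1_SFF": "1/2"
  },
  "clamped": {
    "Cln3": -1
  }
}
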