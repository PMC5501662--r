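{
  "degree": 3,
  "n_patterns": 8,
  "patterns": [
    {
      "pairs": [],
      "terminate": [1, 2, 3],
      "abut": [],
      "group": false
    },
    {
      "pairs": [
        [1, 2]
      ],
      "terminate": 3,
      "abut": [],
      "group": false
    },
    {
      "pairs": [
        [1, 2]
      ],
      "terminate": [],
      "abut": 3,
      "group": false
    },
    {
      "pairs": [
        [1, 3]
      ],
      "terminate": 2,
      "abut": [],
      "group": false
    },
    {
      "pairs": [
        [1, 3]
      ],
      "terminate": [],
      "abut": 2,
      "group": false
    },
    {
      "pairs": [
        [2, 3]
      ],
      "terminate": 1,
      "abut": [],
      "group": false
    },
    {
      "pairs": [
        [2, 3]
      ],
      "terminate": [],
      "abut": 1,
      "group": false
    },
    {
      "pairs": [],
      "terminate": [],
      "abut": [],
      "group": true
    }
  ],
  "note": "Each pattern covers the junction's attachment slots exactly once and carries equal probability."
}
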