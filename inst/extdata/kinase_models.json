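[
  {
    "name": "CK2",
    "kinase_class": "acidophilic",
    "acceptors": [
      "S",
      "T"
    ],
    "w": 7,
    "match_midpoint": 2.5,
    "match_slope": 3,
    "acceptor_weights": {
      "S": 0.5,
      "T": 0.5
    },
    "logodds": [
      {
        "position": 1,
        "residue": "D",
        "value": 1.5
      },
      {
        "position": 2,
        "residue": "D",
        "value": 1.5
      },
      {
        "position": 3,
        "residue": "D",
        "value": 2
      },
      {
        "position": 1,
        "residue": "E",
        "value": 1.5
      },
      {
        "position": 2,
        "residue": "E",
        "value": 1.5
      },
      {
        "position": 3,
        "residue": "E",
        "value": 2
      }
    ]
  },
  {
    "name": "PKA",
    "kinase_class": "basophilic",
    "acceptors": [
      "S",
      "T"
    ],
    "w": 7,
    "match_midpoint": 2,
    "match_slope": 3,
    "acceptor_weights": {
      "S": 0.5,
      "T": 0.5
    },
    "logodds": [
      {
        "position": -3,
        "residue": "K",
        "value": 1
      },
      {
        "position": -2,
        "residue": "K",
        "value": 1
      },
      {
        "position": -3,
        "residue": "R",
        "value": 2
      },
      {
        "position": -2,
        "residue": "R",
        "value": 2
      }
    ]
  },
  {
    "name": "ERK2",
    "kinase_class": "pro_directed",
    "acceptors": [
      "S",
      "T"
    ],
    "w": 7,
    "match_midpoint": 1.75,
    "match_slope": 3,
    "acceptor_weights": {
      "S": 0.5,
      "T": 0.5
    },
    "logodds": [
      {
        "position": -2,
        "residue": "P",
        "value": 1.5
      },
      {
        "position": 1,
        "residue": "P",
        "value": 2
      }
    ]
  },
  {
    "name": "JNK1",
    "kinase_class": "pro_directed",
    "acceptors": [
      "S",
      "T"
    ],
    "w": 7,
    "match_midpoint": 1,
    "match_slope": 3,
    "acceptor_weights": {
      "S": 0.5,
      "T": 0.5
    },
    "logodds": [
      {
        "position": 1,
        "residue": "P",
        "value": 2
      }
    ]
  },
  {
    "name": "p38a",
    "kinase_class": "pro_directed",
    "acceptors": [
      "S",
      "T"
    ],
    "w": 7,
    "match_midpoint": 1.25,
    "match_slope": 3,
    "acceptor_weights": {
      "S": 0.3,
      "T": 0.7
    },
    "logodds": [
      {
        "position": 2,
        "residue": "D",
        "value": 0.5
      },
      {
        "position": 2,
        "residue": "E",
        "value": 0.5
      },
      {
        "position": 1,
        "residue": "P",
        "value": 2
      }
    ]
  },
  {
    "name": "CDK1",
    "kinase_class": "pro_directed",
    "acceptors": [
      "S",
      "T"
    ],
    "w": 7,
    "match_midpoint": 1.75,
    "match_slope": 3,
    "acceptor_weights": {
      "S": 0.5,
      "T": 0.5
    },
    "logodds": [
      {
        "position": 3,
        "residue": "K",
        "value": 1.5
      },
      {
        "position": 1,
        "residue": "P",
        "value": 2
      },
      {
        "position": 3,
        "residue": "R",
        "value": 1.5
      }
    ]
  },
  {
    "name": "SRC",
    "kinase_class": "tyrosine",
    "acceptors": [
      "Y"
    ],
    "w": 7,
    "match_midpoint": 2,
    "match_slope": 3,
    "acceptor_weights": {
      "Y": 1
    },
    "logodds": [
      {
        "position": -2,
        "residue": "D",
        "value": 1.5
      },
      {
        "position": -3,
        "residue": "E",
        "value": 1.5
      },
      {
        "position": -1,
        "residue": "I",
        "value": 1
      },
      {
        "position": -1,
        "residue": "V",
        "value": 1
      }
    ]
  },
  {
    "name": "EGFR",
    "kinase_class": "tyrosine",
    "acceptors": [
      "Y"
    ],
    "w": 7,
    "match_midpoint": 2,
    "match_slope": 3,
    "acceptor_weights": {
      "Y": 1
    },
    "logodds": [
      {
        "position": 1,
        "residue": "D",
        "value": 1.5
      },
      {
        "position": 2,
        "residue": "D",
        "value": 1
      },
      {
        "position": -1,
        "residue": "E",
        "value": 1.5
      },
      {
        "position": 1,
        "residue": "E",
        "value": 1.5
      },
      {
        "position": 2,
        "residue": "E",
        "value": 1
      }
    ]
  }
]
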