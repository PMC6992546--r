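{
  "correlation_strength": 0.5,
  "noise": {
    "cv": [
      0.1
    ],
    "lod": 0.1,
    "blank_offsets": {
      "P": 300,
      "Ca": 150,
      "Zn": 1
    }
  },
  "classes": [
    {
      "botanical_variety": "robinia",
      "country": "Hungary",
      "n_default": 11,
      "element_ranges": {
        "Cl": [51.2, 357.2],
        "K": [132.4, 313.9],
        "Ca": [19.7, 126.9],
        "Fe": [1.5, 5.5],
        "Zn": [0.3, 2.4]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1
      }
    },
    {
      "botanical_variety": "robinia",
      "country": "Italy",
      "n_default": 5,
      "element_ranges": {
        "Cl": [36.1, 96],
        "K": [137, 380.6],
        "Ca": [4.7, 17.2],
        "Fe": [1.4, 2],
        "Zn": [0.6, 1.3]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1
      }
    },
    {
      "botanical_variety": "robinia",
      "country": "Romania",
      "n_default": 3,
      "element_ranges": {
        "Cl": [65.4, 67.6],
        "K": [143.9, 160.3],
        "Ca": [20.9, 37.6],
        "Fe": [2.1, 2.3],
        "Zn": [0.6, 1.1]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1
      }
    },
    {
      "botanical_variety": "orange",
      "country": "Italy",
      "n_default": 6,
      "element_ranges": {
        "Cl": [50, 286.3],
        "K": [137.3, 368.2],
        "Ca": [25.9, 59.9],
        "Fe": [1.7, 3.4],
        "Zn": [0.4, 1.4],
        "Mn": [1.8, 1.8]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1,
        "Mn": 0.166666666666667
      }
    },
    {
      "botanical_variety": "orange",
      "country": "Spain",
      "n_default": 9,
      "element_ranges": {
        "Cl": [49.5, 68.7],
        "K": [180, 271.6],
        "Ca": [39.2, 65.5],
        "Fe": [1.9, 3.5],
        "Zn": [0.4, 1.6]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1
      }
    },
    {
      "botanical_variety": "lavender",
      "country": "France",
      "n_default": 5,
      "element_ranges": {
        "Cl": [62.6, 113.9],
        "K": [167.5, 287.9],
        "Ca": [29.9, 46.6],
        "Fe": [1.7, 3.3],
        "Zn": [0.6, 0.9],
        "Mn": [1, 1]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1,
        "Mn": 0.2
      }
    },
    {
      "botanical_variety": "lavender",
      "country": "Portugal",
      "n_default": 6,
      "element_ranges": {
        "Cl": [93.6, 117],
        "K": [202.6, 316.4],
        "Ca": [19.5, 47.8],
        "Fe": [1.7, 2.2],
        "Zn": [0.5, 2.5],
        "Mn": [1.6, 2.3],
        "Rb": [1.8, 1.8]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1,
        "Mn": 0.833333333333333,
        "Rb": 0.166666666666667
      }
    },
    {
      "botanical_variety": "lavender",
      "country": "Spain",
      "n_default": 5,
      "element_ranges": {
        "Cl": [88.9, 362.5],
        "K": [295.7, 1243.1],
        "Ca": [20.6, 81.3],
        "Fe": [2.3, 6.3],
        "Zn": [0.8, 3.4],
        "Mn": [1.1, 6.2]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1,
        "Mn": 0.6
      }
    },
    {
      "botanical_variety": "rosemary",
      "country": "Spain",
      "n_default": 7,
      "element_ranges": {
        "Cl": [34.3, 119.2],
        "K": [86.4, 183.8],
        "Ca": [17, 83.7],
        "Fe": [1.4, 2.9],
        "Zn": [0.2, 1]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1
      }
    },
    {
      "botanical_variety": "thyme",
      "country": "Spain",
      "n_default": 3,
      "element_ranges": {
        "Cl": [128.8, 284],
        "K": [435.6, 599],
        "Ca": [62.3, 111.5],
        "Fe": [3.1, 3.7],
        "Zn": [1.1, 1.7],
        "Mn": [1.9, 1.9]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1,
        "Mn": 0.333333333333333
      }
    },
    {
      "botanical_variety": "thyme",
      "country": "New Zealand",
      "n_default": 3,
      "element_ranges": {
        "Cl": [48.1, 100.8],
        "K": [450, 553.8],
        "Ca": [21, 62.9],
        "Fe": [1.9, 3.4],
        "Zn": [0.1, 0.7],
        "Mn": [1.1, 2.5]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1,
        "Mn": 0.666666666666667
      }
    },
    {
      "botanical_variety": "manuka",
      "country": "New Zealand",
      "n_default": 7,
      "element_ranges": {
        "Cl": [180.1, 481.6],
        "K": [446.5, 1640.4],
        "Ca": [31.5, 59],
        "Fe": [1.5, 3.5],
        "Zn": [1, 2],
        "Mn": [1.6, 12.8],
        "Rb": [4, 6]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1,
        "Mn": 0.857142857142857,
        "Rb": 0.714285714285714
      }
    },
    {
      "botanical_variety": "chestnut",
      "country": "Italy",
      "n_default": 5,
      "element_ranges": {
        "Cl": [172.4, 575.7],
        "K": [1883.8, 3324.1],
        "Ca": [101, 182.8],
        "Fe": [2.2, 3.6],
        "Zn": [0.8, 2.2],
        "Mn": [1.9, 16.7],
        "Rb": [8.6, 22]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1,
        "Mn": 1,
        "Rb": 1
      }
    },
    {
      "botanical_variety": "chestnut",
      "country": "Spain",
      "n_default": 3,
      "element_ranges": {
        "Cl": [147.1, 273.5],
        "K": [1730.5, 3451.3],
        "Ca": [92.3, 187.7],
        "Fe": [2.9, 5.8],
        "Zn": [0.8, 2.4],
        "Mn": [4.3, 28.4],
        "Rb": [7.2, 16.14]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1,
        "Mn": 1,
        "Rb": 1
      }
    },
    {
      "botanical_variety": "eucalyptus",
      "country": "Spain",
      "n_default": 3,
      "element_ranges": {
        "Cl": [326.7, 443.6],
        "K": [408.1, 740.5],
        "Ca": [92.9, 122.9],
        "Fe": [3, 5.8],
        "Zn": [1.13, 4.3],
        "Mn": [3.8, 5.8],
        "Rb": [1.8, 6.6]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1,
        "Mn": 0.666666666666667,
        "Rb": 0.666666666666667
      }
    },
    {
      "botanical_variety": "lime",
      "country": "Romania",
      "n_default": 5,
      "element_ranges": {
        "Cl": [86.5, 217.7],
        "K": [193, 1034.9],
        "Ca": [41.1, 110.7],
        "Fe": [1.7, 10.3],
        "Zn": [0.3, 1.3]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1
      }
    },
    {
      "botanical_variety": "sunflower",
      "country": "Romania",
      "n_default": 3,
      "element_ranges": {
        "Cl": [208.6, 360.6],
        "K": [293, 360.6],
        "Ca": [118.5, 127.2],
        "Fe": [2.2, 3.7],
        "Zn": [1.3, 2.6],
        "Mn": [2.1, 2.1],
        "Rb": [1.6, 1.6]
      },
      "detect_prob": {
        "Cl": 1,
        "K": 1,
        "Ca": 1,
        "Fe": 1,
        "Zn": 1,
        "Mn": 0.333333333333333,
        "Rb": 0.333333333333333
      }
    }
  ]
}
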