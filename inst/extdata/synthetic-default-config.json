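{
  "seed": 2011,
  "cohort": {
    "n": 10000
  },
  "strategies": {
    "none": {
      "family": "none"
    },
    "assign20": {
      "family": "fixed_risk",
      "threshold": 0.2
    },
    "assign10": {
      "family": "fixed_risk",
      "threshold": 0.1
    },
    "age20": {
      "family": "age_stratified",
      "match": "assign20"
    },
    "age10": {
      "family": "age_stratified",
      "match": "assign10"
    },
    "arr20": {
      "family": "arr",
      "match": "assign20"
    },
    "arr10": {
      "family": "arr",
      "match": "assign10"
    }
  },
  "psa": {
    "iterations": 1000
  },
  "wtp_grid": {
    "from": 0,
    "to": 50000,
    "by": 500
  },
  "note": "synthetic default configuration: all cohort and strategy values are package defaults, not fitted survey parameters"
}
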