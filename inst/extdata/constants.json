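{
  "n_causes_2007": 106,
  "n_causes_2012": 62,
  "n_indicators_2007": 408,
  "n_indicators_2012": 221,
  "n_retained": 164,
  "n_new": 57,
  "n_excluded": 244,
  "per_level_distinct": {
    "1": 93,
    "2": 87,
    "3": 31,
    "4": 10
  },
  "per_group": {
    "adult": {
      "levels": [
        56,
        37,
        27,
        10
      ],
      "cod_total": 130,
      "personal": 26,
      "respondent": 3,
      "context": 10,
      "total": 169
    },
    "child": {
      "levels": [
        34,
        35,
        22,
        10
      ],
      "cod_total": 101,
      "personal": 26,
      "respondent": 3,
      "context": 10,
      "total": 140
    },
    "neonate": {
      "levels": [
        44,
        35,
        15,
        10
      ],
      "cod_total": 104,
      "personal": 26,
      "respondent": 3,
      "context": 10,
      "total": 143
    }
  }
}
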