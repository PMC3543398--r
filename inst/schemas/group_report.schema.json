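{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "GroupRecoveryReport",
  "type": "object",
  "required": ["n_patients", "n_occasions", "mode", "adjust",
               "occasion_summary", "friedman", "pairwise", "fits"],
  "properties": {
    "n_patients": {"type": "integer", "minimum": 2},
    "n_occasions": {"type": "integer", "minimum": 2},
    "mode": {"enum": ["occasion_summary", "pooled"]},
    "adjust": {"enum": ["none", "bonferroni"]},
    "occasion_summary": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["occasion", "mean_day", "median", "q1", "q3"]
      }
    },
    "friedman": {
      "type": "object",
      "required": ["statistic", "df", "p.value"],
      "properties": {
        "statistic": {"type": "number", "minimum": 0},
        "df": {"type": "integer", "minimum": 1},
        "p.value": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "pairwise": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["occasion_1", "occasion_2", "statistic",
                     "p.value", "p.adjusted"]
      }
    },
    "fits": {
      "type": "object",
      "required": ["logarithmic", "linear"],
      "additionalProperties": {
        "type": "object",
        "required": ["kind", "mode", "a", "b", "r_squared", "n"],
        "properties": {
          "r_squared": {"type": "number", "minimum": 0, "maximum": 1}
        }
      }
    }
  }
}
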