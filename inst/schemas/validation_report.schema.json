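{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ValidationReport",
  "type": "object",
  "required": ["threshold", "anchors", "occasions", "n_used",
               "n_skipped", "metrics", "comparison", "records"],
  "properties": {
    "threshold": {"type": "number", "minimum": 0},
    "anchors": {"type": "array", "items": {"type": "integer"}},
    "occasions": {"type": "array", "items": {"type": "integer"}},
    "n_used": {"type": "integer", "minimum": 1},
    "n_skipped": {"type": "integer", "minimum": 0},
    "metrics": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["occasion", "kind", "n", "r_squared", "diff_mean",
                     "diff_sd", "n_correct", "n_total", "pct_within"],
        "properties": {
          "kind": {"enum": ["logarithmic", "linear"]},
          "pct_within": {"type": "number", "minimum": 0, "maximum": 100}
        }
      }
    },
    "comparison": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["occasion", "chi2_stat", "chi2_p"]
      }
    },
    "records": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["patient_id", "occasion", "day", "actual",
                     "predicted_logarithmic", "predicted_linear"]
      }
    }
  }
}
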