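{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "midribr curve export",
  "description": "Per-sample export of a processed leaf midrib: raw digitized key points, corrected key points, the dense smoothed curve with per-node curvature and arc length, and the smoothing iteration report. All coordinates in cm, curvature in 1/cm.",
  "type": "object",
  "required": ["sample_id", "raw_points", "corrected_key_points",
               "dense_nodes", "curvature", "arclength", "n_key", "c",
               "report"],
  "properties": {
    "sample_id": {"type": "string"},
    "raw_points": {
      "type": "array",
      "items": {"type": "array", "items": {"type": "number"}, "minItems": 3, "maxItems": 3}
    },
    "corrected_key_points": {
      "type": "array",
      "items": {"type": "array", "items": {"type": "number"}, "minItems": 3, "maxItems": 3}
    },
    "dense_nodes": {
      "type": "array",
      "description": "n_key + (n_key - 1) * c nodes: corrected key points interleaved with c spline-evaluated nodes per segment",
      "items": {"type": "array", "items": {"type": "number"}, "minItems": 3, "maxItems": 3}
    },
    "curvature": {"type": "array", "items": {"type": "number", "minimum": 0}},
    "arclength": {"type": "array", "items": {"type": "number", "minimum": 0}},
    "n_key": {"type": "integer", "minimum": 2},
    "c": {"type": "integer", "minimum": 1},
    "report": {
      "type": "object",
      "required": ["n_iterations", "converged"],
      "properties": {
        "n_iterations": {"type": "integer", "minimum": 0},
        "converged": {"type": "boolean"},
        "flagged_per_iteration": {"type": "array", "items": {"type": "integer"}},
        "max_curvature_final": {"type": "number"}
      }
    }
  }
}
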