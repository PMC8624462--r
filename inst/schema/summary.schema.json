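{
  "type": "object",
  "required": ["design", "n_observations", "outliers", "rr", "vertical",
               "parallelism"],
  "properties": {
    "design": {
      "type": "object",
      "required": ["n_subjects", "n_operators", "n_sessions"],
      "properties": {
        "n_subjects": {"type": "integer"},
        "n_operators": {"type": "integer"},
        "n_sessions": {"type": "integer"}
      }
    },
    "n_observations": {"type": "integer"},
    "outliers": {
      "type": "object",
      "required": ["n_flagged", "rules"],
      "properties": {
        "n_flagged": {"type": "integer"},
        "rules": {
          "type": "object",
          "required": ["gross_mm", "grubbs_alpha", "mandel_alpha"],
          "properties": {
            "gross_mm": {"type": "number"},
            "grubbs_alpha": {"type": "number"},
            "mandel_alpha": {"type": "number"}
          }
        }
      }
    },
    "rr": {
      "type": "object",
      "required": ["n_records", "worst_ci_repro_mm"],
      "properties": {
        "n_records": {"type": "integer"},
        "worst_ci_repro_mm": {"type": "number"}
      }
    },
    "vertical": {
      "type": "object",
      "required": ["conventional", "novel"],
      "properties": {
        "conventional": {
          "type": "object",
          "required": ["n_records", "max_ci_repro_mm"],
          "properties": {
            "n_records": {"type": "integer"},
            "max_ci_repro_mm": {"type": "number"}
          }
        },
        "novel": {
          "type": "object",
          "required": ["n_records", "max_ci_repro_mm"],
          "properties": {
            "n_records": {"type": "integer"},
            "max_ci_repro_mm": {"type": "number"}
          }
        }
      }
    },
    "parallelism": {
      "type": "object",
      "required": ["mean_abs_angle_deg", "sd_abs_angle_deg",
                   "mean_abs_iaf_l_mm", "mean_abs_iaf_r_mm", "n_subjects"],
      "properties": {
        "mean_abs_angle_deg": {"type": "number"},
        "sd_abs_angle_deg": {"type": "number"},
        "mean_abs_iaf_l_mm": {"type": "number"},
        "mean_abs_iaf_r_mm": {"type": "number"},
        "n_subjects": {"type": "integer"}
      }
    }
  }
}
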