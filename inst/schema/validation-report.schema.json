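{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "luscab validation report",
  "description": "JSON report written by write_report(). Percentages are numbers on the 0-100 scale rounded half away from zero to one decimal; proportions (AUC), statistics and p-values keep full precision.",
  "type": "object",
  "required": ["cohort_summary", "group_comparisons", "accuracy_by_outcome", "survival", "provenance"],
  "properties": {
    "cohort_summary": {
      "type": "object",
      "required": ["n", "age_months", "wdf", "luscab"],
      "properties": {
        "n": {"type": "integer", "minimum": 1},
        "age_months": {"$ref": "#/definitions/median_iqr"},
        "age_lt_1mo_pct": {"$ref": "#/definitions/percent"},
        "male_pct": {"$ref": "#/definitions/percent"},
        "wdf": {"$ref": "#/definitions/median_iqr"},
        "luscab": {"$ref": "#/definitions/median_iqr"},
        "sao2": {"type": "object"},
        "admitted_pct": {"$ref": "#/definitions/percent"},
        "oxygen_therapy_pct": {"$ref": "#/definitions/percent"},
        "respiratory_support_pct": {"$ref": "#/definitions/percent"},
        "ncpap_bipap_mv_pct": {"$ref": "#/definitions/percent"},
        "tier_counts": {"type": "object"},
        "sao2_luscab_spearman": {"type": "object"}
      }
    },
    "group_comparisons": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "properties": {
          "variable": {"type": "string"},
          "test": {"enum": ["kruskal_wallis", "chi_square", "fisher_exact", "spearman"]},
          "statistic": {"type": ["number", "null"]},
          "p_value": {"type": "number", "minimum": 0, "maximum": 1}
        }
      }
    },
    "accuracy_by_outcome": {
      "type": "object",
      "required": ["admission", "oxygen_therapy", "respiratory_support", "ncpap_bipap_mv"],
      "additionalProperties": {
        "type": "object",
        "required": ["outcome", "evaluable"],
        "properties": {
          "outcome": {"type": "string"},
          "evaluable": {"type": "boolean"},
          "n_pos": {"type": "integer"},
          "n_neg": {"type": "integer"},
          "confusion": {
            "type": "object",
            "required": ["tp", "fp", "tn", "fn"],
            "additionalProperties": {"type": "integer", "minimum": 0}
          },
          "sensitivity_pct": {"$ref": "#/definitions/percent"},
          "specificity_pct": {"$ref": "#/definitions/percent"},
          "ppv_pct": {"$ref": "#/definitions/percent"},
          "npv_pct": {"$ref": "#/definitions/percent"},
          "auc": {"type": "number", "minimum": 0, "maximum": 1},
          "auc_ci_low": {"type": "number", "minimum": 0, "maximum": 1},
          "auc_ci_high": {"type": "number", "minimum": 0, "maximum": 1}
        }
      }
    },
    "survival": {
      "type": "object",
      "required": ["respiratory_support", "ncpap_bipap_mv"],
      "additionalProperties": {
        "type": "object",
        "required": ["horizon_h", "evaluable"],
        "properties": {
          "horizon_h": {"type": "number"},
          "evaluable": {"type": "boolean"},
          "high_risk": {"$ref": "#/definitions/km_group"},
          "low_risk": {"$ref": "#/definitions/km_group"},
          "logrank": {
            "type": "object",
            "properties": {
              "chi_square": {"type": "number", "minimum": 0},
              "df": {"type": "integer"},
              "p_value": {"type": "number", "minimum": 0, "maximum": 1}
            }
          }
        }
      }
    },
    "provenance": {
      "type": "object",
      "required": ["cutoff", "horizon_h", "consolidation_policy", "package_version"],
      "properties": {
        "input": {"type": "string"},
        "n": {"type": "integer"},
        "seed": {"type": "integer"},
        "cutoff": {"type": "number"},
        "horizon_h": {"type": "number"},
        "consolidation_policy": {"enum": ["additive", "exclusive_max"]},
        "package_version": {"type": "string"}
      }
    }
  },
  "definitions": {
    "percent": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
    "median_iqr": {
      "type": "object",
      "properties": {
        "n": {"type": "integer"},
        "median": {"type": "number"},
        "q1": {"type": "number"},
        "q3": {"type": "number"}
      }
    },
    "km_group": {
      "type": ["object", "null"],
      "properties": {
        "n": {"type": "integer"},
        "n_events": {"type": "integer"},
        "event_times_h": {"type": "array", "items": {"type": "number"}},
        "survival": {"type": "array", "items": {"type": "number"}},
        "at_risk": {"type": "array", "items": {"type": "integer"}},
        "n_events_at": {"type": "array", "items": {"type": "integer"}},
        "event_free_at_horizon_pct": {"$ref": "#/definitions/percent"}
      }
    }
  }
}
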