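{
  "table_version": "saps2-legall-1993",
  "comment": "SAPS-II category points. Interval components use right-open intervals: points[i] applies to values in [breaks[i-1], breaks[i]); the first interval is (-Inf, breaks[1]) and the last is [breaks[last], Inf). pao2_fio2 is scored only for mechanically ventilated (or CPAP) patients; non-ventilated patients score 0 on this component.",
  "components": {
    "age": {
      "type": "interval", "units": "years",
      "breaks": [40, 60, 70, 75, 80],
      "points": [0, 7, 12, 15, 16, 18]
    },
    "heart_rate": {
      "type": "interval", "units": "bpm",
      "breaks": [40, 70, 120, 160],
      "points": [11, 2, 0, 4, 7]
    },
    "systolic_bp": {
      "type": "interval", "units": "mmHg",
      "breaks": [70, 100, 200],
      "points": [13, 5, 0, 2]
    },
    "temperature": {
      "type": "interval", "units": "degC",
      "breaks": [39],
      "points": [0, 3]
    },
    "pao2_fio2_ratio": {
      "type": "interval", "units": "mmHg",
      "breaks": [100, 200],
      "points": [11, 9, 6],
      "requires_ventilation": true,
      "not_ventilated_points": 0
    },
    "urine_output": {
      "type": "interval", "units": "mL/day",
      "breaks": [500, 1000],
      "points": [11, 4, 0]
    },
    "bun": {
      "type": "interval", "units": "mg/dL",
      "breaks": [28, 84],
      "points": [0, 6, 10]
    },
    "sodium": {
      "type": "interval", "units": "mEq/L",
      "breaks": [125, 145],
      "points": [5, 0, 1]
    },
    "potassium": {
      "type": "interval", "units": "mEq/L",
      "breaks": [3, 5],
      "points": [3, 0, 3]
    },
    "bicarbonate": {
      "type": "interval", "units": "mEq/L",
      "breaks": [15, 20],
      "points": [6, 3, 0]
    },
    "bilirubin": {
      "type": "interval", "units": "mg/dL",
      "breaks": [4, 6],
      "points": [0, 4, 9]
    },
    "wbc": {
      "type": "interval", "units": "10^3/uL",
      "breaks": [1, 20],
      "points": [12, 0, 3]
    },
    "gcs": {
      "type": "interval", "units": "points",
      "breaks": [6, 9, 11, 14],
      "points": [26, 13, 7, 5, 0]
    },
    "chronic_disease": {
      "type": "categorical",
      "points": {
        "none": 0,
        "metastatic_cancer": 9,
        "hematologic_malignancy": 10,
        "aids": 17
      }
    },
    "admission_type": {
      "type": "categorical",
      "points": {
        "scheduled_surgical": 0,
        "medical": 6,
        "unscheduled_surgical": 8
      }
    }
  }
}
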