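{
  "name": "default",
  "version": 1,
  "description": "Group-level oculomotor profiles: per-parameter mean and SD for the four diagnostic groups, plus demographics, neuropsychological summaries and antisaccade/memory success probabilities. Values are [mean, sd].",
  "classifier_features": [
    "pro_latency_h", "pro_latency_v", "return_latency_h", "return_latency_v",
    "pro_pos_error_h", "pro_pos_error_v", "pro_neg_error_h", "pro_neg_error_v",
    "pursuit_gain_h", "pursuit_gain_v", "pursuit_error_h", "pursuit_error_v",
    "anti_pos_error_h", "anti_pos_error_v", "anti_neg_error_h", "anti_neg_error_v",
    "pct_correct_anti", "pct_corrected_anti", "pct_successful_anti",
    "pct_correct_memory"
  ],
  "groups": {
    "control": {
      "n": 29,
      "demographics": {
        "age": [66.21, 5.51],
        "pct_female": 79.31,
        "disease_duration": null,
        "sedatives": [0.14, 0.44]
      },
      "neuropsych": {
        "mmse": [28.96, 0.92],
        "rocft_copy": [32.86, 2.85],
        "symbol_digit": [39.55, 14.14]
      },
      "params": {
        "pro_latency_h": [257.50, 52.24],
        "pro_latency_v": [264.80, 34.70],
        "return_latency_h": [250.59, 72.96],
        "return_latency_v": [250.19, 36.30],
        "pro_pos_error_h": [0.67, 0.73],
        "pro_pos_error_v": [0.54, 0.39],
        "pro_neg_error_h": [-0.41, 0.62],
        "pro_neg_error_v": [-0.67, 1.44],
        "pursuit_gain_h": [0.79, 0.18],
        "pursuit_gain_v": [0.75, 0.33],
        "pursuit_error_h": [3.11, 2.01],
        "pursuit_error_v": [2.23, 1.29],
        "pct_correct_anti": [26.38, 18.75],
        "pct_corrected_anti": [96.06, 11.11],
        "pct_successful_anti": [92.24, 14.92],
        "anti_corrected_latency_h": [587.14, 183.32],
        "anti_corrected_latency_v": [550.64, 90.90],
        "anti_pos_error_h": [2.43, 2.73],
        "anti_pos_error_v": [1.72, 1.40],
        "anti_neg_error_h": [-1.79, 1.10],
        "anti_neg_error_v": [-1.58, 0.66],
        "pct_correct_memory": [94.14, 9.74],
        "mem_latency_h": [410.26, 197.59],
        "mem_latency_v": [384.39, 115.94],
        "mem_pos_error_h": [1.48, 0.76],
        "mem_pos_error_v": [0.98, 0.56],
        "mem_neg_error_h": [-0.72, 0.67],
        "mem_neg_error_v": [-0.98, 1.37]
      },
      "early_rate": 0.03
    },
    "AD": {
      "n": 18,
      "demographics": {
        "age": [68.17, 6.96],
        "pct_female": 66.67,
        "disease_duration": [4.94, 1.73],
        "sedatives": [1.06, 0.87]
      },
      "neuropsych": {
        "mmse": [16.72, 5.23],
        "rocft_copy": [20.13, 11.14],
        "symbol_digit": [16.43, 12.33]
      },
      "params": {
        "pro_latency_h": [409.60, 226.60],
        "pro_latency_v": [315.14, 100.48],
        "return_latency_h": [361.06, 202.30],
        "return_latency_v": [313.01, 133.12],
        "pro_pos_error_h": [1.06, 1.43],
        "pro_pos_error_v": [0.95, 1.17],
        "pro_neg_error_h": [-3.23, 4.38],
        "pro_neg_error_v": [-1.55, 2.39],
        "pursuit_gain_h": [0.89, 0.78],
        "pursuit_gain_v": [0.83, 1.02],
        "pursuit_error_h": [6.03, 3.01],
        "pursuit_error_v": [3.66, 1.44],
        "pct_correct_anti": [4.00, 5.41],
        "pct_corrected_anti": [46.08, 34.94],
        "pct_successful_anti": [36.44, 30.77],
        "anti_corrected_latency_h": [1680.38, 879.79],
        "anti_corrected_latency_v": [1485.63, 1066.28],
        "anti_pos_error_h": [4.56, 3.70],
        "anti_pos_error_v": [4.87, 2.72],
        "anti_neg_error_h": [-11.15, 10.66],
        "anti_neg_error_v": [-5.88, 5.32],
        "pct_correct_memory": [26.00, 19.41],
        "mem_latency_h": [852.58, 314.01],
        "mem_latency_v": [1163.14, 903.67],
        "mem_pos_error_h": [2.53, 3.39],
        "mem_pos_error_v": [1.44, 1.71],
        "mem_neg_error_h": [-3.82, 2.11],
        "mem_neg_error_v": [-2.17, 1.30]
      },
      "early_rate": 0.10
    },
    "bvFTD": {
      "n": 18,
      "demographics": {
        "age": [68.83, 8.71],
        "pct_female": 22.22,
        "disease_duration": [5.56, 3.15],
        "sedatives": [2.06, 1.11]
      },
      "neuropsych": {
        "mmse": [23.50, 2.73],
        "rocft_copy": [25.06, 9.24],
        "symbol_digit": [19.33, 9.25]
      },
      "params": {
        "pro_latency_h": [266.23, 34.20],
        "pro_latency_v": [282.79, 42.25],
        "return_latency_h": [245.48, 28.48],
        "return_latency_v": [280.70, 56.47],
        "pro_pos_error_h": [0.69, 0.62],
        "pro_pos_error_v": [0.60, 0.51],
        "pro_neg_error_h": [-1.60, 3.44],
        "pro_neg_error_v": [-0.47, 0.37],
        "pursuit_gain_h": [0.87, 0.29],
        "pursuit_gain_v": [0.56, 0.60],
        "pursuit_error_h": [2.89, 1.93],
        "pursuit_error_v": [2.56, 1.34],
        "pct_correct_anti": [7.50, 10.80],
        "pct_corrected_anti": [76.15, 33.96],
        "pct_successful_anti": [70.00, 34.88],
        "anti_corrected_latency_h": [1112.34, 959.28],
        "anti_corrected_latency_v": [937.94, 564.51],
        "anti_pos_error_h": [8.40, 3.41],
        "anti_pos_error_v": [3.46, 1.26],
        "anti_neg_error_h": [-5.18, 9.81],
        "anti_neg_error_v": [-5.01, 5.99],
        "pct_correct_memory": [40.36, 25.15],
        "mem_latency_h": [695.44, 343.24],
        "mem_latency_v": [866.05, 461.76],
        "mem_pos_error_h": [1.38, 1.37],
        "mem_pos_error_v": [0.91, 0.64],
        "mem_neg_error_h": [-2.37, 1.91],
        "mem_neg_error_v": [-2.30, 1.47]
      },
      "early_rate": 0.05
    },
    "svPPA": {
      "n": 7,
      "demographics": {
        "age": [70.86, 8.11],
        "pct_female": 57.14,
        "disease_duration": [6.00, 3.79],
        "sedatives": [0.86, 0.90]
      },
      "neuropsych": {
        "mmse": [22.43, 4.65],
        "rocft_copy": [28.75, 7.09],
        "symbol_digit": [21.60, 10.21]
      },
      "params": {
        "pro_latency_h": [336.62, 160.48],
        "pro_latency_v": [322.63, 119.10],
        "return_latency_h": [353.50, 219.70],
        "return_latency_v": [327.88, 114.81],
        "pro_pos_error_h": [1.34, 1.08],
        "pro_pos_error_v": [0.78, 0.45],
        "pro_neg_error_h": [-0.68, 0.60],
        "pro_neg_error_v": [-0.48, 0.34],
        "pursuit_gain_h": [0.67, 0.24],
        "pursuit_gain_v": [0.73, 0.13],
        "pursuit_error_h": [3.12, 1.51],
        "pursuit_error_v": [2.95, 1.30],
        "pct_correct_anti": [25.00, 29.33],
        "pct_corrected_anti": [100.00, 0.00],
        "pct_successful_anti": [83.33, 16.63],
        "anti_corrected_latency_h": [676.84, 173.65],
        "anti_corrected_latency_v": [560.45, 139.67],
        "anti_pos_error_h": [5.69, 4.25],
        "anti_pos_error_v": [2.50, 1.62],
        "anti_neg_error_h": [-3.76, 1.94],
        "anti_neg_error_v": [-1.48, 0.73],
        "pct_correct_memory": [64.17, 36.94],
        "mem_latency_h": [517.37, 245.48],
        "mem_latency_v": [492.58, 332.35],
        "mem_pos_error_h": [1.53, 0.75],
        "mem_pos_error_v": [0.88, 0.44],
        "mem_neg_error_h": [-0.86, 0.54],
        "mem_neg_error_v": [-1.41, 1.52]
      },
      "early_rate": 0.10
    }
  }
}
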