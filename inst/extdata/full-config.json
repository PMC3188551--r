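{
  "preset": "full",
  "stimuli": {
    "size": 128,
    "n_identity": 40,
    "n_expression": 40
  },
  "retina": {
    "normalise": true
  },
  "layers": [
    {
      "dims": [32, 32],
      "n_connections": 272,
      "radius": 6,
      "freq_connections": [201, 50, 13, 8],
      "lateral": {
        "sigma_E": 0.7,
        "delta_E": 5.35,
        "sigma_I": 1.38,
        "delta_I": 1.5
      },
      "sigmoid": {
        "percentile": 95,
        "beta": 190
      }
    },
    {
      "dims": [32, 32],
      "n_connections": 100,
      "radius": 6,
      "lateral": {
        "sigma_E": 0.55,
        "delta_E": 33.15,
        "sigma_I": 2.7,
        "delta_I": 1.5
      },
      "sigmoid": {
        "percentile": 95,
        "beta": 40
      }
    },
    {
      "dims": [32, 32],
      "n_connections": 100,
      "radius": 9,
      "lateral": {
        "sigma_E": 0.4,
        "delta_E": 117.57,
        "sigma_I": 4,
        "delta_I": 1.6
      },
      "sigmoid": {
        "percentile": 95,
        "beta": 75
      }
    },
    {
      "dims": [32, 32],
      "n_connections": 100,
      "radius": 12,
      "lateral": {
        "sigma_E": 0.6,
        "delta_E": 120.12,
        "sigma_I": 6,
        "delta_I": 1.4
      },
      "sigmoid": {
        "percentile": 95,
        "beta": 26
      }
    }
  ],
  "training": {
    "epochs": [50, 100, 100, 75],
    "learning_rate": 0.1,
    "sparseness": 0.05,
    "shuffle": true
  },
  "analysis": {
    "response_threshold": 0.5,
    "min_region_length": 2,
    "n_blocks": 5,
    "n_permutations": 999
  }
}
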