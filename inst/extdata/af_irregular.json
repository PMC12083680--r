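{
  "la_ees": 0.45,
  "la_v0": 0,
  "la_a_res": 0.5,
  "la_b_res": 0.049,
  "chambers": {
    "LA": {
      "onset": 0.74,
      "duration": 0.2,
      "viscous_resistance": 0.01,
      "relax_tau": 0
    },
    "LV": {
      "ees": 2.5,
      "v0": 5,
      "a_res": 0.35,
      "b_res": 0.033,
      "onset": 0,
      "duration": 0.3,
      "viscous_resistance": 0,
      "relax_tau": 0.12
    },
    "RA": {
      "ees": 0.3,
      "v0": 0,
      "a_res": 0.4,
      "b_res": 0.04,
      "onset": 0.74,
      "duration": 0.2,
      "viscous_resistance": 0.01,
      "relax_tau": 0
    },
    "RV": {
      "ees": 0.6,
      "v0": 5,
      "a_res": 0.1,
      "b_res": 0.025,
      "onset": 0,
      "duration": 0.3,
      "viscous_resistance": 0,
      "relax_tau": 0.12
    }
  },
  "compartments": {
    "SA": {
      "compliance": 1.6,
      "resistance": 1,
      "unstressed": 300
    },
    "SV": {
      "compliance": 50,
      "resistance": 0.05,
      "unstressed": 2000
    },
    "PA": {
      "compliance": 5,
      "resistance": 0.1,
      "unstressed": 50
    },
    "PV": {
      "compliance": 0.8,
      "resistance": 0.01,
      "unstressed": 300
    }
  },
  "valves": {
    "MV": {
      "resistance": 0.01
    },
    "AoV": {
      "resistance": 0.006
    },
    "TV": {
      "resistance": 0.005
    },
    "PuV": {
      "resistance": 0.003
    }
  },
  "rhythm": {
    "cycle_lengths": [0.375, 0.4, 0.5],
    "atrial_active": false,
    "av_delay": 0.16
  },
  "total_volume": 3600,
  "gating": "additive"
}
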