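{
  "version": "1.0",
  "comment": "Default synthetic-observer population. Pursuit parameters are typical oculomotor values chosen so the second-order condition shows longer latency, lower acceleration/gain, and more catch-up saccades than first-order, and so the acceleration phase outlasts the 100-ms initial-acceleration window. Perceptual gains gamma are fixed per (condition, velocity) so the veridical-minus-bias structure of mean reaction times decreases with velocity in every condition, is later for pursuit than fixation, and earlier for second- than first-order at 3 deg/s.",
  "conditions": {
    "fixation": {
      "latency_mean_ms": null,
      "latency_sd_ms": null,
      "accel_mean": null,
      "pursuit_gain": null,
      "saccade_rate_hz": 0.0,
      "blink_prob": 0.05,
      "gamma": { "3": 1.12284, "4": 0.92047, "5": 0.83403 }
    },
    "pursuit_first_order": {
      "latency_mean_ms": 130,
      "latency_sd_ms": 15,
      "accel_mean": 25,
      "pursuit_gain": 0.95,
      "saccade_rate_hz": 1.0,
      "blink_prob": 0.05,
      "gamma": { "3": 1.05256, "4": 0.89111, "5": 0.75700 }
    },
    "pursuit_second_order": {
      "latency_mean_ms": 160,
      "latency_sd_ms": 20,
      "accel_mean": 20,
      "pursuit_gain": 0.75,
      "saccade_rate_hz": 2.0,
      "blink_prob": 0.05,
      "gamma": { "3": 1.13921, "4": 0.88005, "5": 0.74635 }
    }
  },
  "shared": {
    "fixation_noise_sd_deg": 0.005,
    "timing_cv": 0.10,
    "motor_sd_ms": 30,
    "post_occlusion_tau_ms": 300,
    "saccade_duration_ms": 30,
    "saccade_min_amplitude_deg": 1.0,
    "blink_duration_range_ms": [100, 300],
    "trace_tmax_ms": 1000
  },
  "between_observer": {
    "latency_sd_ms": 10,
    "accel_cv": 0.15,
    "gain_sd": 0.05,
    "gamma_cv": 0.05,
    "saccade_rate_cv": 0.2
  }
}
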