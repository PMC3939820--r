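{
  "units": {
    "time": "h",
    "concentration": "mM",
    "response": "AU"
  },
  "provenance": "synthetic: scenario A, noiseless default design",
  "n_records": 186,
  "clipped": 0,
  "noise": {
    "kind": "none",
    "sigma": 0,
    "seed": {}
  },
  "spec": {
    "control": {
      "Xm": 1,
      "vm": 0.25,
      "lam": 3
    },
    "effect_on_Xm": {
      "K": 1,
      "m": 5,
      "a": 2,
      "direction": "attenuate"
    },
    "effect_on_vm": {
      "K": 1,
      "m": 4,
      "a": 2,
      "direction": "attenuate"
    },
    "effect_on_lag": {
      "K": 1,
      "m": 2,
      "a": 2,
      "direction": "amplify"
    },
    "parameterization": "lag",
    "allow_superunity_K": false
  }
}
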