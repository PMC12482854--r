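{
  "model_id": "surrogate-v1",
  "synthetic": true,
  "comment": "SYNTHETIC surrogate neurodegeneration model. Age-linear normative means and SDs for ICV-normalized volumes (fractions) of the three atrophy-sensitive structures, plus a logistic link on the mean pathological z-score. This is NOT the published HAVAs lifespan model; supply a file with the same schema to use a different model.",
  "age_reference": 45,
  "logistic_scale": 1.0,
  "structures": {
    "hippocampus": {
      "mean_at_reference": 0.0052, "slope_per_year": -8.0e-06,
      "sd": 5.5e-04, "direction": -1
    },
    "amygdala": {
      "mean_at_reference": 0.0024, "slope_per_year": -3.0e-06,
      "sd": 3.0e-04, "direction": -1
    },
    "inferior_lateral_ventricle": {
      "mean_at_reference": 0.0006, "slope_per_year": 1.2e-05,
      "sd": 3.0e-04, "direction": 1
    }
  }
}
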