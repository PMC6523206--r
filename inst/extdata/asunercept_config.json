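{
  "drug": {
    "molecular_weight": 84082.0,
    "fraction_unbound": 1.0,
    "solute_radius": 4.01,
    "cd95l_kd": 1.91,
    "cd95l_koff": 9.70e-5,
    "asgr_cl_spec": 2.43e-4,
    "fcrn_kd_lysosomal": 1.73,
    "fcrn_kd_serum": 999999.0,
    "fcrn_kass": 0.87,
    "gfr_fraction": 0.0
  },
  "batch": {"batch_id": "high_sialylation", "sa_glycan_ratio": 0.64},
  "expression": {
    "cd95l_organs": ["bone", "brain", "gonads", "kidney", "lung"],
    "cd95l_relative_expression": 1.0,
    "cd95l_reference_concentration": 1.0,
    "asgr_organ": "liver",
    "asgr_reference_concentration": 1.0
  },
  "individual": {"age": 30, "sex": "male"},
  "schedule": {"dose_mg": 400, "n_doses": 1, "interval_h": 168,
               "infusion_h": 1.0},
  "output_times_h": {"to": 2016, "by": 24},
  "pediatrics": {
    "bands": [[1, 2], [2, 5], [5, 9], [9, 12], [12, 18]],
    "n_per_band": 50,
    "adult_n": 58,
    "rounding_step": 0.2
  }
}
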