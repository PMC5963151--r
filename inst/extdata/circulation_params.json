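{
  "circulation": {
    "r_mi": 0.02,
    "r_ao": 0.006,
    "r_tr": 0.015,
    "r_pu": 0.001,
    "r_sa": 1.3,
    "r_sv": 0.05,
    "r_pa": 0.01,
    "r_pv": 0.02,
    "c_sa": 6,
    "c_sv": 15,
    "c_ra": 6,
    "c_la": 6,
    "c_pa": 16,
    "c_pv": 8,
    "total_blood_mL": 950,
    "v0_la": 30,
    "v0_ra": 20,
    "lvad_flow_lpm": 0
  },
  "ventricle_lv": {
    "v0": 20,
    "e_es": 2.7,
    "edp_a": 0.55,
    "edp_b": 0.135,
    "v0d": 95,
    "act_k": "Inf"
  },
  "ventricle_rv": {
    "v0": 40,
    "e_es": 0.36,
    "edp_a": 1,
    "edp_b": 0.09,
    "v0d": 115,
    "act_k": 0.5
  }
}
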