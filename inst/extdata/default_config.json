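{
  "interventions": [
    {
      "name": "CBT",
      "target": "PD",
      "uptake_usual": 0.088,
      "uptake_alt": 0.088,
      "base_adherence": 0.7,
      "dropout": 0,
      "annual_cost": 1176,
      "cost_timing": "recurring",
      "cost_cv": 0.25,
      "utility_gain": 0.0327,
      "transition_rr": null,
      "gain_se": 0.00654
    },
    {
      "name": "SSRI",
      "target": "PD",
      "uptake_usual": 0.092,
      "uptake_alt": 0.092,
      "base_adherence": 0.7,
      "dropout": 0.18,
      "annual_cost": 1128,
      "cost_timing": "recurring",
      "cost_cv": 0.25,
      "utility_gain": 0.045,
      "transition_rr": null,
      "gain_se": 0.009
    },
    {
      "name": "TCA",
      "target": "PD",
      "uptake_usual": 0.024,
      "uptake_alt": 0.024,
      "base_adherence": 0.7,
      "dropout": 0.3,
      "annual_cost": 1200,
      "cost_timing": "recurring",
      "cost_cv": 0.25,
      "utility_gain": 0.0445,
      "transition_rr": null,
      "gain_se": 0.0089
    },
    {
      "name": "combination",
      "target": "PD",
      "uptake_usual": 0.09,
      "uptake_alt": 0.09,
      "base_adherence": 0.7,
      "dropout": 0,
      "annual_cost": 2315,
      "cost_timing": "recurring",
      "cost_cv": 0.25,
      "utility_gain": 0.0568,
      "transition_rr": null,
      "gain_se": 0.01136
    },
    {
      "name": "early_intervention",
      "target": "STHPD",
      "uptake_usual": 0,
      "uptake_alt": 0.1,
      "base_adherence": 0.7,
      "dropout": 0,
      "annual_cost": 905,
      "cost_timing": "once",
      "cost_cv": 0.25,
      "utility_gain": 0.0655,
      "transition_rr": 0.538,
      "gain_se": 0.0131
    }
  ],
  "state_econ": [
    {
      "state": "PF",
      "utility": 0.869,
      "utility_se": 0.0054,
      "cost_direct_medical": 340,
      "cost_direct_nonmedical": 99,
      "cost_indirect_nonmedical": 6643,
      "cost_cv": 0.25
    },
    {
      "state": "STHPD",
      "utility": 0.73,
      "utility_se": 0.037,
      "cost_direct_medical": 1503,
      "cost_direct_nonmedical": 494,
      "cost_indirect_nonmedical": 9741,
      "cost_cv": 0.25
    },
    {
      "state": "PD",
      "utility": 0.66,
      "utility_se": 0.03,
      "cost_direct_medical": 666,
      "cost_direct_nonmedical": 858,
      "cost_indirect_nonmedical": 16771,
      "cost_cv": 0.25
    },
    {
      "state": "DEAD",
      "utility": 0,
      "utility_se": 0,
      "cost_direct_medical": 0,
      "cost_direct_nonmedical": 0,
      "cost_indirect_nonmedical": 0,
      "cost_cv": 0
    }
  ],
  "transitions": {
    "p_pf_sthpd": 0.0016,
    "p_sthpd_pf": 0.0815,
    "p_sthpd_pd": 0.6037,
    "p_pd_sthpd": 0.5214,
    "p_death": 0.0028
  },
  "settings": {
    "horizon": 5,
    "cycle_length": 1,
    "discount_rate_costs": 0.04,
    "discount_rate_effects": 0.015,
    "wtp_threshold": 20000,
    "prevalence_sthpd": 0.019,
    "prevalence_pd": 0.022,
    "utilities_corrected": true,
    "psa_iterations": 10000,
    "reward_timing": "end"
  }
}
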