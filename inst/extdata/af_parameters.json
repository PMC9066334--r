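{
  "schema": "afcea-parameters-v1",
  "description": "Base-case inputs for the AF mHealth-vs-usual-care Markov cohort model. All probabilities are per monthly cycle as fractions (the published percent strings are kept in 'source'); costs in 2021 US $.",
  "parameters": {
    "p_is_usual": {"value": 0.00244, "low": 0.0020, "high": 0.0029, "dist": "beta", "source": "IS monthly % 0.244 (0.20-0.29)"},
    "p_ich_usual": {"value": 0.00024, "low": 0.0002, "high": 0.0003, "dist": "beta", "source": "ICH monthly % 0.024 (0.02-0.03)"},
    "p_gib_usual": {"value": 0.00034, "low": 0.0003, "high": 0.0004, "dist": "beta", "source": "GIB monthly % 0.034 (0.03-0.04)"},
    "hr_is": {"value": 0.11, "low": 0.05, "high": 0.27, "dist": "lognormal", "source": "HR IS 0.11 (0.05-0.27)"},
    "hr_ich": {"value": 0.5, "low": 0.0, "high": 1.0, "dist": "triangular", "source": "HR ICH 0.5 (0-1), assumption"},
    "hr_gib": {"value": 0.37, "low": 0.2, "high": 0.7, "dist": "lognormal", "source": "HR GIB 0.37 (0.2-0.7)"},
    "compliance": {"value": 0.708, "low": 0.50, "high": 1.00, "dist": "beta", "source": "compliance % 70.8 (50-100)"},
    "prop_is_minor": {"value": 0.516, "low": 0.439, "high": 0.558, "dist": "dirichlet", "group": "prop_is", "source": "IS minor % 51.6 (43.9-55.8)"},
    "prop_is_major": {"value": 0.402, "low": 0.402, "high": 0.417, "dist": "dirichlet", "group": "prop_is", "source": "IS major % 40.2 (40.2-41.7)"},
    "prop_is_fatal": {"value": 0.082, "low": 0.025, "high": 0.163, "dist": "dirichlet", "group": "prop_is", "source": "IS fatal % 8.2 (2.5-16.3)"},
    "prop_ich_minor": {"value": 0.495, "low": 0.33, "high": 0.63, "dist": "dirichlet", "group": "prop_ich", "source": "ICH minor % 49.5 (33-63)"},
    "prop_ich_major": {"value": 0.141, "low": 0.09, "high": 0.214, "dist": "dirichlet", "group": "prop_ich", "source": "ICH major % 14.1 (9-21.4)"},
    "prop_ich_fatal": {"value": 0.364, "low": 0.156, "high": 0.580, "dist": "dirichlet", "group": "prop_ich", "source": "ICH fatal % 36.4 (15.6-58.0)"},
    "p_recur_is": {"value": 0.0068, "low": 0.0068, "high": 0.0070, "dist": "beta", "source": "IS recurrence monthly % 0.68 (0.68-0.70)"},
    "p_recur_ich": {"value": 0.0073, "low": 0.0070, "high": 0.0076, "dist": "beta", "source": "ICH recurrence monthly % 0.73 (0.70-0.76)"},
    "prop_is_after_is": {"value": 0.91, "low": 0.73, "high": 1.00, "dist": "beta", "pair": "prop_ich_after_is", "source": "IS after IS % 91 (73-100)"},
    "prop_ich_after_is": {"value": 0.09, "low": 0.00, "high": 0.27, "dist": "complement", "pair": "prop_is_after_is", "source": "ICH after IS % 9 (0-27)"},
    "prop_is_after_ich": {"value": 0.44, "low": 0.33, "high": 0.55, "dist": "beta", "pair": "prop_ich_after_ich", "source": "IS after ICH % 44 (33-55)"},
    "prop_ich_after_ich": {"value": 0.56, "low": 0.45, "high": 0.67, "dist": "complement", "pair": "prop_is_after_ich", "source": "ICH after ICH % 56 (45-67)"},
    "mortality_65_69": {"value": 0.0010, "low": 0.0008, "high": 0.0012, "dist": "triangular", "band": "65-69", "source": "monthly % 0.10 (0.08-0.12)"},
    "mortality_70_74": {"value": 0.0026, "low": 0.0020, "high": 0.0031, "dist": "triangular", "band": "70-74", "source": "monthly % 0.26 (0.20-0.31)"},
    "mortality_75_79": {"value": 0.0041, "low": 0.0033, "high": 0.0050, "dist": "triangular", "band": "75-79", "source": "monthly % 0.41 (0.33-0.50)"},
    "mortality_80_84": {"value": 0.0071, "low": 0.0057, "high": 0.0085, "dist": "triangular", "band": "80-84", "source": "monthly % 0.71 (0.57-0.85)"},
    "mortality_85_89": {"value": 0.0106, "low": 0.0085, "high": 0.0127, "dist": "triangular", "band": "85-89", "source": "monthly % 1.06 (0.85-1.27)"},
    "mortality_90_94": {"value": 0.0159, "low": 0.0127, "high": 0.0191, "dist": "triangular", "band": "90-94", "source": "monthly % 1.59 (1.27-1.91)"},
    "mortality_95plus": {"value": 0.0181, "low": 0.0145, "high": 0.0217, "dist": "triangular", "band": ">95", "source": "monthly % 1.81 (1.45-2.17)"},
    "hr_af_mortality": {"value": 1.87, "low": 1.09, "high": 3.20, "dist": "lognormal", "source": "all-cause death HR, AF vs no AF 1.87 (95% CI 1.09-3.20)"},
    "rr_gib_death": {"value": 3.5, "low": 2.8, "high": 4.2, "dist": "lognormal", "source": "RR of death with vs without GIB 3.5 (2.8-4.2)"},
    "u_af": {"value": 0.9, "low": 0.8, "high": 1.0, "dist": "uniform", "source": "utility event-free AF 0.9 (0.8-1)"},
    "u_is_minor": {"value": 0.75, "low": 0.6, "high": 0.92, "dist": "uniform", "source": "utility minor IS 0.75 (0.6-0.92)"},
    "u_is_major": {"value": 0.39, "low": 0.31, "high": 0.47, "dist": "uniform", "source": "utility major IS 0.39 (0.31-0.47)"},
    "u_ich_minor": {"value": 0.75, "low": 0.6, "high": 0.92, "dist": "uniform", "source": "utility minor ICH 0.75 (0.6-0.92)"},
    "u_ich_major": {"value": 0.39, "low": 0.31, "high": 0.47, "dist": "uniform", "source": "utility major ICH 0.39 (0.31-0.47)"},
    "du_gib": {"value": 0.16, "low": 0.13, "high": 0.19, "dist": "uniform", "source": "utility decrement of GIB 0.16 (0.13-0.19), 14 days"},
    "c_event_is_minor": {"value": 3277, "low": 2622, "high": 3932, "dist": "lognormal", "source": "event cost minor IS 3277 (2622-3932)"},
    "c_event_is_major": {"value": 6676, "low": 5341, "high": 8012, "dist": "lognormal", "source": "event cost major IS 6676 (5341-8012)"},
    "c_event_ich_minor": {"value": 5284, "low": 4227, "high": 6340, "dist": "lognormal", "source": "event cost minor ICH 5284 (4227-6340)"},
    "c_event_ich_major": {"value": 10567, "low": 8454, "high": 12680, "dist": "lognormal", "source": "event cost major ICH 10567 (8454-12680)"},
    "c_event_gib": {"value": 3443, "low": 2754, "high": 4131, "dist": "lognormal", "source": "event cost GIB 3443 (2754-4131)"},
    "c_death": {"value": 5849, "low": 4679, "high": 7019, "dist": "lognormal", "source": "all-cause death cost 5849 (4679-7019)"},
    "c_anticoag_monthly": {"value": 249, "low": 199, "high": 299, "dist": "lognormal", "source": "anticoagulation per month 249 (199-299)"},
    "c_fu_is_minor": {"value": 328, "low": 262, "high": 393, "dist": "lognormal", "source": "follow-up minor IS per month 328 (262-393)"},
    "c_fu_is_major": {"value": 668, "low": 534, "high": 801, "dist": "lognormal", "source": "follow-up major IS per month 668 (534-801)"},
    "c_fu_ich_minor": {"value": 528, "low": 422, "high": 634, "dist": "lognormal", "source": "follow-up minor ICH per month 528 (422-634)"},
    "c_fu_ich_major": {"value": 1057, "low": 845, "high": 1268, "dist": "lognormal", "source": "follow-up major ICH per month 1057 (845-1268)"},
    "c_mhealth_setup": {"value": 80, "low": 64, "high": 96, "dist": "lognormal", "source": "site implementation per patient, one-time 80 (64-96)"},
    "c_mhealth_monthly": {"value": 15, "low": 12, "high": 18, "dist": "lognormal", "source": "managing per month 15 (12-18)"},
    "discount_annual": {"value": 0.035, "dist": "fixed", "source": "3.5% per annum"},
    "wtp": {"value": 33438, "dist": "fixed", "source": "US $33,438 per QALY (3x GDP per capita)"},
    "horizon_months": {"value": 360, "dist": "fixed", "source": "30-year horizon, monthly cycles"},
    "start_age_years": {"value": 68, "dist": "fixed", "source": "cohort mean age 68"}
  }
}
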