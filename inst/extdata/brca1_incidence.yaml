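# Synthetic BRCA1-carrier-like age-specific breast cancer incidence
# (events/person-year), piecewise constant over 5-year bands (single band
# below age 20). Shaped to give a cumulative risk of ~72% by age 80.
# These values are configuration for simulation and weighting, not claims.
age_breaks: [0, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80]
hazard: [0.0001, 0.003, 0.008, 0.016, 0.025, 0.030, 0.032, 0.030, 0.028, 0.025, 0.022, 0.020, 0.018]
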