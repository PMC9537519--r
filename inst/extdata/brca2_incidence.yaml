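# Synthetic BRCA2-carrier-like age-specific breast cancer incidence
# (events/person-year), piecewise constant over 5-year bands (single band
# below age 20). Shaped to give a cumulative risk of ~69% by age 80.
# These values are configuration for simulation and weighting, not claims.
age_breaks: [0, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80]
hazard: [0.0001, 0.001, 0.003, 0.007, 0.012, 0.018, 0.024, 0.028, 0.030, 0.030, 0.028, 0.026, 0.024]
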