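# Hypothetical two-stratum population: same exposure prevalence and
# never-smoker mortality as the observed sample, but smoker mortality 0.50
# in both strata (the sample's lower smoker risks are the footprint of
# health selection).
label: hypothetical population
reference: nonsmoker
strata:
  - id: black
    "N": 1000
    prevalence: {nonsmoker: 0.65, smoker: 0.35}
    qx: {nonsmoker: 0.230769230769230770, smoker: 0.5}
  - id: white
    "N": 4000
    prevalence: {nonsmoker: 0.80, smoker: 0.20}
    qx: {nonsmoker: 0.15625, smoker: 0.5}
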