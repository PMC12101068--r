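tubes:
  tube1:
    markers:
    - kappa
    - lambda
    - CD19
    - CD5
    - CD79b
    - CD20
    - CD45
    fluorochromes:
    - FITC
    - PE
    - PC5.5
    - PE-Cy7
    - APC
    - PB
    - HV500
  tube2:
    markers:
    - FMC7
    - CD38
    - CD19
    - CD5
    - CD23
    - CD43
    - CD45
    fluorochromes:
    - FITC
    - PE
    - PC5.5
    - PE-Cy7
    - APC
    - APC-AF750
    - HV500
  tube3:
    markers:
    - kappa
    - lambda
    - CD19
    - CD13
    - CD22
    - CD27
    - CD45
    fluorochromes:
    - FITC
    - PE
    - PC5.5
    - PE-Cy7
    - APC
    - BV421
    - HV500
channel_map: []
absent: []
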