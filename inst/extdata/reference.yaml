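mfi:
  CD19: 1250.8802631
  CD20: 1563.4506767
  CD22: 910.5023164
  CD79b: 825.9136986
  CD27: 400.6975424
  FMC7: 908.1795364
  kappa: 522.2912163
  lambda: 358.1709555
  CD13: .na.real
  CD5: .na.real
  CD23: .na.real
  CD43: .na.real
  CD38: .na.real
boundaries:
  weak: 0.5
  strong: 2.0
source: package default (synthetic healthy-control scale)
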