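patient_id,compartment,light_chain,clonal_fraction,CD19_pct,CD19_mfi,FMC7_pct,FMC7_mfi,CD22_pct,CD22_mfi,CD79b_pct,CD79b_mfi,CD27_pct,CD27_mfi,CD13_pct,label
WM_BM_01,BM,kappa,62,97,360,12,150,96,225,99,3200,9,120,4,WM
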