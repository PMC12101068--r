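patient_id,compartment,light_chain,clonal_fraction,CD19_pct,CD19_mfi,FMC7_pct,FMC7_mfi,CD22_pct,CD22_mfi,CD79b_pct,CD79b_mfi,CD27_pct,CD27_mfi,CD13_pct,label
WM_PB_01,PB,kappa,7,96,350,10,140,95,210,99,3350,11,130,5,WM
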