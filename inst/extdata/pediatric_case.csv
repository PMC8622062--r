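id,age,sex,mechanism,temperature_c,potassium_mmol_l,cpr_min,outcome,cpc
pediatric_boy,6,male,submersion,17,7.6,95,survived,1
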