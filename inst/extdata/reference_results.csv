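quantity,group,value
fa1_over_mean_min_pct,female LFW,1.07
fa1_over_mean_max_pct,male SF,2.67
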