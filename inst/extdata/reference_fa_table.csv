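sex,trait,n,replicates,mean_error,mean_mm,ms_interaction,ms_error,f_interaction,fa1,fa4a,fa10a,me3,me3_known_discrepancy
male,AFW,31,3,0.03,4.41,3.98e-5,2.99e-6,13.30,0.076,0.088,0.004,16.4,TRUE
male,LFW,30,3,0.03,3.79,3.33e-3,6.52e-4,5.10,0.063,0.066,0.034,19.6,FALSE
male,SF,30,3,0.006,0.45,4.25e-4,5.67e-5,7.50,0.012,0.013,0.012,13.3,FALSE
female,AFW,28,3,0.03,5.16,1.38e-5,8.27e-7,16.9,0.065,0.062,0.002,5.9,FALSE
female,LFW,28,3,0.02,4.01,2.35e-3,4.51e-4,5.20,0.043,0.046,0.028,19.2,FALSE
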