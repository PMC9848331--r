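variant,second_half_mean_rmsd,wt_second_half_mean_rmsd,rmsf_peak_max,rmsf_peak_first,rmsf_peak_last,wt_rmsf_at_peak
K303N,1.0,1.0,NA,NA,NA,NA
N373S,1.0,1.0,NA,NA,NA,NA
D375N,1.0,1.0,NA,NA,NA,NA
D375H,1.0,1.0,NA,NA,NA,NA
E399K,1.0,1.0,NA,NA,NA,NA
T390I,1.0,1.0,NA,NA,NA,NA
V407A,1.0,1.0,NA,NA,NA,NA
T400S,1.0,1.0,NA,NA,NA,NA
W402S,1.0,1.0,NA,NA,NA,NA
N301S,1.6,1.0,3.0,375,379,0.8
S307F,1.6,1.0,3.0,375,379,0.8
V384F,1.6,1.0,3.0,375,379,0.8
T306I,1.6,1.0,3.0,375,379,0.8
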