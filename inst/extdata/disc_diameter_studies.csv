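label,mean_mm,se_mm,n
study1,1.97,0.003,3918
study2,1.88,0.023,118
study3,1.88,0.009,475
study4,1.98,0.036,62
study5,1.82,0.015,110
study6,1.96,0.018,122
study7,1.97,0.031,88
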