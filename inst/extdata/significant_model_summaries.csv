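dataset,target,mae_mean,mae_sd,d_me,d_lr
Be,bitter,0.490,0.176,1.344,1.372
Be,sweet,0.600,0.282,0.651,0.660
Co,acid,0.459,0.178,0.844,0.841
BeCo,astringent,0.598,0.132,0.595,0.717
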