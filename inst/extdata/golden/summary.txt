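truth	a=0.05	R=30	C=20000
median_a_hat	0.0497417638626
median_R_hat	29.8622715932
median_UC_hat	19999.1794114
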