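{"slope_nN_per_A":183.333333333333,"intercept_nN":0}
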