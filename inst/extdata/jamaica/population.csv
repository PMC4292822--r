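age_band,sex,count
all,all,1330000
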