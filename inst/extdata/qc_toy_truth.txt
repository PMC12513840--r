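v07
v08
v09
v10
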