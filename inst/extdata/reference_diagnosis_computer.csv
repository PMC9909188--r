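tp,fn,fp,tn
48,12,19,44
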