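drug: D1 targets=R_UP
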