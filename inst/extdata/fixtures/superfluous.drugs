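drug: DK targets=R_IN1
drug: DL targets=R_IN1,R_IN2
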