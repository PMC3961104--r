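# pepforge cap template v1 (neutral N-terminus, -NH2)
cap neutral N NH2
atom H1 H C CA N 1.010 109.5 180
atom H2 H C CA N 1.010 109.5 60
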