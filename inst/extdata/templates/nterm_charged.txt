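# pepforge cap template v1 (charged N-terminus, -NH3+)
# attached to the first residue's N after its backbone is placed
cap charged N NH3
atom H1 H C CA N 1.010 109.5 180
atom H2 H C CA N 1.010 109.5 60
atom H3 H C CA N 1.010 109.5 -60
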