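# pepforge cap template v1 (acetyl, CH3-C(=O)-)
cap methyl N ACE
atom CH3 C . . . 0 0 0
atom C   C . . CH3 1.522 0 0
atom O   O . CH3 C 1.231 120.8 0
atom HH31 H O C CH3 1.090 109.5 60
atom HH32 H O C CH3 1.090 109.5 180
atom HH33 H O C CH3 1.090 109.5 -60
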