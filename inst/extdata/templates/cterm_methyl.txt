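# pepforge cap template v1 (N-methyl amide, -NH-CH3)
cap methyl C NME
atom N   N  -N  -CA -C  1.329 116.2 psi-
atom CH3 C  -CA -C   N  1.449 121.7 -180
atom H   H  -CA -C   N  1.010 119.2 0
atom HH31 H -C   N   CH3 1.090 109.5 180
atom HH32 H -C   N   CH3 1.090 109.5 60
atom HH33 H -C   N   CH3 1.090 109.5 -60
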