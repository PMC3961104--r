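# pepforge cap template v1 (neutral C-terminus, -COOH)
cap neutral C OXT
atom OXT O -N -CA -C 1.306 113.0 psi-
atom HXT H -CA -C OXT 0.974 110.5 180
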