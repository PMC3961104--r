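# pepforge cap template v1 (charged C-terminus, -COO-)
cap charged C OXT
atom OXT O -N -CA -C 1.249 117.0 psi-
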