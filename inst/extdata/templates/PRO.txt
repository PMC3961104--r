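# pepforge residue template v1
# columns: atom <name> <element> <ref_a> <ref_b> <ref_c> <length A> <angle deg> <dihedral>
# dihedral: absolute degrees or a torsion reference (phi, psi, omega,
#   chi1..chi4, psi- = psi of the preceding unit), with optional +/- offset.
# refs prefixed '-' live in the preceding residue or cap.
residue PRO P
atom N   N  -N  -CA -C  1.338 119.3 psi-
atom CA  C  -CA -C   N  1.468 122.6 omega
atom C   C  -C   N   CA 1.524 112.1 phi
atom O   O   N   CA  C  1.231 120.2 psi+180
atom CB  C   N   C   CA 1.530 111.5 120.2
atom HA  H   N   C   CA 1.090 108.8 -118.1
atom CD  C  -C   CA  N  1.473 112.0 180.0
atom CG  C   N   CA  CB 1.495 98.7204 -15.0000
atom HB2 H   N   CA  CB 1.090 110.0 105.0000
atom HB3 H   N   CA  CB 1.090 110.0 -135.0000
atom HG2 H   CA  CB  CG 1.090 110.0 153.9137
atom HG3 H   CA  CB  CG 1.090 110.0 -86.0863
atom HD2 H   CA  N   CD 1.090 110.0 146.2138
atom HD3 H   CA  N   CD 1.090 110.0 -93.7862
ring CG CD 1.503
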