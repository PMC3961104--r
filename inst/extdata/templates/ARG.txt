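# pepforge residue template v1
# columns: atom <name> <element> <ref_a> <ref_b> <ref_c> <length A> <angle deg> <dihedral>
# dihedral: absolute degrees or a torsion reference (phi, psi, omega,
#   chi1..chi4, psi- = psi of the preceding unit), with optional +/- offset.
# refs prefixed '-' live in the preceding residue or cap.
residue ARG R
chi chi1 N CA CB CG
chi chi2 CA CB CG CD
chi chi3 CB CG CD NE
chi chi4 CG CD NE CZ
default_chi 180 180 180 180
atom N   N  -N  -CA -C  1.329 116.2 psi-
atom CA  C  -CA -C   N  1.458 121.7 omega
atom C   C  -C   N   CA 1.525 111.2 phi
atom O   O   N   CA  C  1.231 120.8 psi+180
atom H   H  -CA -C   N  1.010 119.2 omega+180
atom CB  C   N   C   CA 1.530 110.1 122.55
atom HA  H   N   C   CA 1.090 107.9 -116.5
atom CG  C   N   CA  CB 1.530 114.1 chi1
atom HB2 H   N   CA  CB 1.090 109.4 chi1+120
atom HB3 H   N   CA  CB 1.090 109.4 chi1-120
atom CD  C   CA  CB  CG 1.530 111.3 chi2
atom HG2 H   CA  CB  CG 1.090 109.4 chi2+120
atom HG3 H   CA  CB  CG 1.090 109.4 chi2-120
atom NE  N   CB  CG  CD 1.460 112.0 chi3
atom HD2 H   CB  CG  CD 1.090 109.4 chi3+120
atom HD3 H   CB  CG  CD 1.090 109.4 chi3-120
atom CZ  C   CG  CD  NE 1.326 124.2 chi4
atom HE  H   CG  CD  NE 1.010 117.9 chi4+180
atom NH1 N   CD  NE  CZ 1.326 120.0 0
atom NH2 N   CD  NE  CZ 1.326 120.0 180
atom HH11 H  NE  CZ  NH1 1.010 120.0 0
atom HH12 H  NE  CZ  NH1 1.010 120.0 180
atom HH21 H  NE  CZ  NH2 1.010 120.0 0
atom HH22 H  NE  CZ  NH2 1.010 120.0 180
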