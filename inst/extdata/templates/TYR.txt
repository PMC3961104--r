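# pepforge residue template v1
# columns: atom <name> <element> <ref_a> <ref_b> <ref_c> <length A> <angle deg> <dihedral>
# dihedral: absolute degrees or a torsion reference (phi, psi, omega,
#   chi1..chi4, psi- = psi of the preceding unit), with optional +/- offset.
# refs prefixed '-' live in the preceding residue or cap.
residue TYR Y
chi chi1 N CA CB CG
chi chi2 CA CB CG CD1
default_chi 180 90
atom N   N  -N  -CA -C  1.329 116.2 psi-
atom CA  C  -CA -C   N  1.458 121.7 omega
atom C   C  -C   N   CA 1.525 111.2 phi
atom O   O   N   CA  C  1.231 120.8 psi+180
atom H   H  -CA -C   N  1.010 119.2 omega+180
atom CB  C   N   C   CA 1.530 110.1 122.55
atom HA  H   N   C   CA 1.090 107.9 -116.5
atom CG  C   N   CA  CB 1.502 113.8 chi1
atom HB2 H   N   CA  CB 1.090 109.4 chi1+120
atom HB3 H   N   CA  CB 1.090 109.4 chi1-120
atom CD1 C   CA  CB  CG 1.390 120.8 chi2
atom CD2 C   CA  CB  CG 1.390 120.8 chi2+180
atom CE1 C   CB  CG  CD1 1.390 120.7 180
atom CE2 C   CB  CG  CD2 1.390 120.7 180
atom CZ  C   CG  CD1 CE1 1.390 120.0 0
atom OH  O   CD1 CE1 CZ 1.376 120.0 180
atom HD1 H   CB  CG  CD1 1.080 119.6 0
atom HD2 H   CB  CG  CD2 1.080 119.6 0
atom HE1 H   CG  CD1 CE1 1.080 120.0 180
atom HE2 H   CG  CD2 CE2 1.080 120.0 180
atom HH  H   CE1 CZ  OH 0.967 110.0 0
ring CZ CE2 1.390
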