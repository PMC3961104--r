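# pepforge residue template v1
# columns: atom <name> <element> <ref_a> <ref_b> <ref_c> <length A> <angle deg> <dihedral>
# dihedral: absolute degrees or a torsion reference (phi, psi, omega,
#   chi1..chi4, psi- = psi of the preceding unit), with optional +/- offset.
# refs prefixed '-' live in the preceding residue or cap.
residue ILE I
chi chi1 N CA CB CG1
chi chi2 CA CB CG1 CD1
default_chi 180 180
atom N   N  -N  -CA -C  1.329 116.2 psi-
atom CA  C  -CA -C   N  1.458 121.7 omega
atom C   C  -C   N   CA 1.525 111.2 phi
atom O   O   N   CA  C  1.231 120.8 psi+180
atom H   H  -CA -C   N  1.010 119.2 omega+180
atom CB  C   N   C   CA 1.530 110.1 122.55
atom HA  H   N   C   CA 1.090 107.9 -116.5
atom CG1 C   N   CA  CB 1.530 110.4 chi1
atom CG2 C   N   CA  CB 1.521 110.5 chi1-120
atom HB  H   N   CA  CB 1.090 108.5 chi1+120
atom CD1 C   CA  CB  CG1 1.513 113.9 chi2
atom HG12 H  CA  CB  CG1 1.090 109.4 chi2+120
atom HG13 H  CA  CB  CG1 1.090 109.4 chi2-120
atom HG21 H  CA  CB  CG2 1.090 109.5 180
atom HG22 H  CA  CB  CG2 1.090 109.5 60
atom HG23 H  CA  CB  CG2 1.090 109.5 -60
atom HD11 H  CB  CG1 CD1 1.090 109.5 180
atom HD12 H  CB  CG1 CD1 1.090 109.5 60
atom HD13 H  CB  CG1 CD1 1.090 109.5 -60
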