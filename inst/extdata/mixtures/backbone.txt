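# pepforge backbone torsion mixture v1
# von Mises mixture over (phi, psi) per residue type; one component per row
# columns: residue(one-letter) weight mean_phi mean_psi kappa_phi kappa_psi
# Components sit at the conventional Ramachandran basins: alpha (-63,-43),
# beta (-120,135), left-handed alpha (60,45). Glycine is phi-symmetric;
# proline's phi is pinned near -65. These are replaceable defaults, not
# fitted densities; users may point the sampler at their own table.
A 0.33 -63 -43 10 8
A 0.52 -120 135 3.5 3.5
A 0.15 60 45 14 14
C 0.33 -63 -43 10 8
C 0.52 -120 135 3.5 3.5
C 0.15 60 45 14 14
D 0.33 -63 -43 10 8
D 0.52 -120 135 3.5 3.5
D 0.15 60 45 14 14
E 0.33 -63 -43 10 8
E 0.52 -120 135 3.5 3.5
E 0.15 60 45 14 14
F 0.33 -63 -43 10 8
F 0.52 -120 135 3.5 3.5
F 0.15 60 45 14 14
G 0.30 -85 100 3 3
G 0.30 85 -100 3 3
G 0.20 -70 -30 4 4
G 0.20 70 30 4 4
H 0.33 -63 -43 10 8
H 0.52 -120 135 3.5 3.5
H 0.15 60 45 14 14
I 0.33 -63 -43 10 8
I 0.52 -120 135 3.5 3.5
I 0.15 60 45 14 14
K 0.33 -63 -43 10 8
K 0.52 -120 135 3.5 3.5
K 0.15 60 45 14 14
L 0.33 -63 -43 10 8
L 0.52 -120 135 3.5 3.5
L 0.15 60 45 14 14
M 0.33 -63 -43 10 8
M 0.52 -120 135 3.5 3.5
M 0.15 60 45 14 14
N 0.33 -63 -43 10 8
N 0.52 -120 135 3.5 3.5
N 0.15 60 45 14 14
P 0.45 -65 -35 40 8
P 0.55 -65 150 40 5
Q 0.33 -63 -43 10 8
Q 0.52 -120 135 3.5 3.5
Q 0.15 60 45 14 14
R 0.33 -63 -43 10 8
R 0.52 -120 135 3.5 3.5
R 0.15 60 45 14 14
S 0.33 -63 -43 10 8
S 0.52 -120 135 3.5 3.5
S 0.15 60 45 14 14
T 0.33 -63 -43 10 8
T 0.52 -120 135 3.5 3.5
T 0.15 60 45 14 14
V 0.33 -63 -43 10 8
V 0.52 -120 135 3.5 3.5
V 0.15 60 45 14 14
W 0.33 -63 -43 10 8
W 0.52 -120 135 3.5 3.5
W 0.15 60 45 14 14
Y 0.33 -63 -43 10 8
Y 0.52 -120 135 3.5 3.5
Y 0.15 60 45 14 14
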