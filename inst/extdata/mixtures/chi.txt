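# pepforge side-chain torsion mixture v1
# von Mises mixture over the full chi vector per residue type; one component
# per row: residue weight mean_1 .. mean_k kappa_1 .. kappa_k
# chi1 components sit at the staggered rotamers gauche-(-60)/trans(180)/
# gauche+(+60); distal sp3 torsions default to trans, terminal sp2 torsions
# to broad components near +/-90 or 0. Replaceable defaults, not fits.
S 0.50 -60 18
S 0.35 180 18
S 0.15 60 18
C 0.50 -60 18
C 0.35 180 18
C 0.15 60 18
T 0.50 -60 18
T 0.35 180 18
T 0.15 60 18
V 0.20 -60 18
V 0.70 180 18
V 0.10 60 18
L 0.60 -60 175 12 12
L 0.30 180 65 12 12
L 0.10 60 180 8 8
I 0.55 -60 170 12 12
I 0.30 180 165 12 12
I 0.15 60 170 8 8
M 0.45 -60 180 180 10 8 4
M 0.35 180 180 180 10 8 4
M 0.20 60 180 180 8 8 4
D 0.50 -60 0 12 2
D 0.35 180 0 12 2
D 0.15 60 0 8 2
N 0.50 -60 0 12 2
N 0.35 180 0 12 2
N 0.15 60 0 8 2
E 0.45 -60 180 0 10 8 2
E 0.40 180 180 0 10 8 2
E 0.15 60 180 0 8 8 2
Q 0.45 -60 180 0 10 8 2
Q 0.40 180 180 0 10 8 2
Q 0.15 60 180 0 8 8 2
K 0.45 -60 180 180 180 10 8 8 6
K 0.40 180 180 180 180 10 8 8 6
K 0.15 60 180 180 180 8 8 8 6
R 0.45 -60 180 180 180 10 8 6 4
R 0.40 180 180 180 180 10 8 6 4
R 0.15 60 180 180 180 8 8 6 4
H 0.50 -60 90 12 3
H 0.35 180 90 12 3
H 0.15 60 90 8 3
F 0.50 -60 90 12 4
F 0.35 180 90 12 4
F 0.15 60 90 8 4
Y 0.50 -60 90 12 4
Y 0.35 180 90 12 4
Y 0.15 60 90 8 4
W 0.50 -60 90 12 4
W 0.35 180 -90 12 4
W 0.15 60 90 8 4
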