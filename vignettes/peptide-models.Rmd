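---
title: "Peptide model construction, sampling and regularization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide model construction, sampling and regularization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepforge)
```

`pepforge` builds capped peptide fragments with exact torsion control,
samples realistic conformations from continuous angular distributions, and
removes steric clashes while holding every torsion fixed. This vignette is
the package's account of how each of those pieces works, which parameters
matter, and where the design was genuinely open.

## Geometry engine

Atoms are placed by the Natural Extension Reference Frame construction:
given three previously placed reference atoms *a*, *b*, *c*, a new atom *d*
is positioned from its bond length |*c*–*d*|, bond angle ∠(*b*,*c*,*d*) and
dihedral (*a*,*b*,*c*,*d*). Torsions follow the IUPAC sign convention
(looking from *b* to *c*, clockwise rotation of the far bond is positive)
and live in the canonical range [−180°, 180°); −180° is the canonical
representation of trans, so the builder's default ω = −180° is stored
verbatim. The sign convention was cross-checked against an independent
structural-bioinformatics implementation during development, and the test
suite asserts the NeRF round trip (place, then re-measure) to 10⁻⁶ in all
three internal coordinates over 1000 random draws.

Torsion changes are rigid branch rotations: to set a torsion across the
bond *b*–*c*, the connected component on the *c* side (after deleting the
edge) is rotated about the bond axis by the difference between the target
and the measured value. This changes exactly one controllable torsion at a
time and provably leaves every bond length and bond angle untouched, which
is what makes "set then get" exact to machine precision. A torsion whose
central bond lies in a ring cannot be rotated rigidly; such torsions are
registered as non-settable.

## Residue and cap templates

Each of the 20 standard residues (and the six caps) ships as a plain-text
internal-coordinate table under `inst/extdata/templates/`: one row per
atom with its three reference atoms, bond length, bond angle and a
dihedral that is either absolute or an expression in a controllable
torsion (`phi`, `psi+180`, `chi1-120`, ...). The numerical values are
idealized protein stereochemistry in the spirit of the standard
restraint compilations used by refinement programs; they are internally
consistent rather than fitted, since all downstream contracts are about
torsions, which the templates parameterize exactly. Conventions fixed at
design time:

* **Torsion quadruples.** φ(i) = C(i−1)–N–Cα–C, ψ(i) = N–Cα–C–N(i+1),
  ω(i) = Cα(i−1)–C(i−1)–N–Cα (the peptide bond *preceding* residue i, so
  `set_bb_angles(res, c(phi, psi, omega))` controls the bond through which
  residue `res` is attached); χ quadruples are the standard IUPAC ones.
  Methyl-cap heavy atoms stand in for missing neighbours (the acetyl
  carbonyl C plays C(0), the N-methyl N plays N(n+1)); at a free carboxyl
  terminus OXT plays N(n+1), which keeps ψ of the last residue defined and
  settable. At a free amine terminus nothing can play C(0), so φ and ω of
  residue 1 are undefined (`NA`) and attempting to set them is an error.
* **Chirality.** All residues are built as L-amino acids; the Cα improper
  dihedral (N, C, Cα, Cβ) is +122.6° and the signed volume
  det[N−Cα, C−Cα, Cβ−Cα] is positive, both verified against an
  independently generated L-alanine reference geometry and asserted for
  every residue type in the tests. Threonine and isoleucine Cβ
  stereochemistry (CG2 at χ₁−120°) was checked the same way.
* **Proline.** The pyrrolidine ring is template-fixed. Its ring torsion
  was solved numerically at build time so the Cγ–Cδ closure bond is exact;
  φ is built at −65° (a ring-compatible value, unlike the generic −120°
  default) and is not settable; no χ angles are exposed. Proline directly
  at a charged/neutral N-terminus is not supported (its backbone N has no
  room for the extra protons in the template scheme); use a methyl cap.
* **Protonation states.** Asp/Glu are built charged (−1), Lys/Arg charged
  (+1), histidine as the neutral Nε2–H tautomer. These fixed choices feed
  the automatic charge assignment of the QM deck writers: total charge =
  cap contributions (+1 charged N-terminus, −1 charged C-terminus) plus
  side-chain formal charges.
* **Default torsions.** Backbone (φ, ψ, ω) = (−120°, 140°, −180°), an
  extended β-strand; default χ values are template data chosen near trans
  (sp³ chains) or perpendicular/planar (sp² termini) so that neighbouring
  side chains of a freshly built peptide do not clash.

## Conformational sampling

Backbone (φ, ψ) pairs and χ vectors are drawn from mixtures of
independent-per-dimension von Mises distributions. The shipped parameter
tables (`inst/extdata/mixtures/`) place components at the conventional
Ramachandran basins — α (−63°, −43°), β (−120°, 135°), left-handed α
(60°, 45°) — with weights 0.33/0.52/0.15 for generic residues, a
φ-symmetric four-component table for glycine, and a φ-pinned (κ = 40)
two-component table for proline; χ mixtures sit at the staggered rotamers
g⁻/t/g⁺ (−60°/180°/60°) with sp² terminal torsions broadened. These are
deliberately *conventional defaults, not fitted densities*: they give the
sampler realistic support and let every distributional contract be tested
exactly against the configured parameters, but no numerical agreement with
any trained model of protein angle statistics is claimed. Users can
supply their own tables in the same plain-text format.

Technical choices:

* Densities are per radian in every dimension (a *d*-dimensional mixture
  integrates to 1 over the torus in radians); `mixture_density()` exposes
  them, and the reported log-likelihood of `get_sample()` is the exact log
  joint density of the returned angles, verified in the tests against an
  independent evaluation to 10⁻⁹.
* Sampling uses the Best–Fisher (1979) wrapped-Cauchy rejection envelope,
  driven by R's global random number stream, so `set_seed()` makes every
  downstream draw bit-reproducible. The sampler was validated by
  chi-square goodness of fit against quadrature of the configured density
  (10⁶ draws during development; 10⁴ per residue type in the suite, with
  small-expectation cells pooled per Cochran's rule).
* Backbone-dependent χ sampling re-weights rotamer components by the
  current backbone basin (gauche⁻ favoured in the helical basin, trans in
  the extended basin, factor 2, renormalized). This is the simplest
  mechanism honouring backbone dependence; it is a stand-in for a learned
  joint model, and the log-likelihood accounts for it exactly.
* Sampling a proline backbone applies ψ only (φ is ring-locked); the
  returned pair reports the measured ring φ.

What passing these tests shows — and does not show — about real data: the
generator demonstrates correct *mechanics* (seeded determinism, exact
application of sampled angles, distributional fidelity to the configured
mixtures). It does not claim that the default mixtures reproduce the
empirical Ramachandran or rotamer statistics of the PDB.

## Energy model and optimizer

The shipped force field exists to *remove clashes under torsion
restraints*, not to rank conformers:

| term | form | parameters |
|---|---|---|
| bonds | k_b (r − r₀)² | k_b = 300 kcal mol⁻¹ Å⁻², r₀ from templates |
| angles | k_a (θ − θ₀)² | k_a = 80 kcal mol⁻¹ rad⁻², θ₀ from templates |
| torsions | (V/2)(1 + cos 3φ) | V = 0.02 kcal mol⁻¹ per quadruple |
| sterics | ε (σ/r)¹² | ε = 0.1 kcal mol⁻¹, σ from Bondi radii, 1-2/1-3 excluded, 1-4 × 0.5 |

Reference values come from the idealized template geometry (obtained from
a fresh default build, which any conformer of the same sequence shares,
because torsion moves never alter bonds or angles). The torsion amplitude
is kept small on purpose: cosine torsion potentials act *against* the
user's chosen torsion values during restrained minimization, which is
exactly what a regularizer must not do; the term is retained (non-zero) so
its analytic gradient stays exercised. Analytic gradients of every term
match central finite differences to 10⁻⁵ relative in the suite. The
energy backend is deliberately modular — `optimize_peptide()` and
`regularize()` only consume an energy/gradient evaluator — so a
full-featured molecular-mechanics implementation can stand behind the same
interface; all optimization contracts in the tests (descent, restraint
fidelity, clash relief) are backend-agnostic.

Minimization is Polak–Ribière conjugate gradients with an Armijo
backtracking line search, refined by a secant step towards the exact line
minimum, and diagonally preconditioned by a per-atom curvature estimate
from the stiff terms (bonds, angles, restraints, close contacts). The
preconditioning matters: torsion restraints are up to 10⁶ kcal mol⁻¹
rad⁻² stiff during regularization, and unpreconditioned CG crawls on such
a spectrum. Convergence follows the ΔE criterion: the run stops when the
energy decrease of an accepted step falls below `tol` (default 10⁻⁶
kcal/mol) or after `max_steps` (default 500) steps. The optimizer is
deterministic.

Constrained optimization (`constraint = TRUE`) adds harmonic restraints
k·Δ² (Δ the wrapped deviation in radians) on every controllable torsion at
its stored target. The default k = 500 kcal mol⁻¹ rad⁻² keeps every
restrained torsion within about a degree of its target even on badly
clashed structures (a stiffness sweep during development showed ~3.5° at
k = 50 and ~2.2° at k = 200 on the clash fixture); harmonic restraints
never hold torsions exactly, which is what motivates regularization.

## Regularization

`regularize()` alternates, for up to `cycles` (default 10) iterations:

1. a restrained conjugate-gradient minimization of `steps_per_cycle`
   (default 50) steps, with the restraint stiffness multiplied by 4 each
   cycle (starting at 200, capped at 10⁶ kcal mol⁻¹ rad⁻²) — a standard
   penalty-method schedule under which the constraint violation shrinks
   geometrically while bonds and angles stay free to relax away from
   clashes;
2. an exact reset of every controllable torsion to its target by rigid
   branch rotation.

The loop stops early once the *pre-reset* maximum torsion deviation drops
below 0.002°, the self-consistency criterion; after the final reset every
controllable torsion equals its target to machine precision. On the
package's synthetic clash fixture — a methyl-capped Trp–Asp–Gly conformer
whose backbone angles drive the C-terminal cap amide hydrogen onto the
residue-1 carbonyl oxygen at ≈1.6 Å — default regularization relieves the
contact to beyond 2 Å while finishing with a pre-reset deviation below
0.002°, and the suite asserts both.

One honest caveat, recorded here rather than hidden: within the default
10 × 50-step budget the soft collective modes (1-4 repulsion against
angle bending) are not fully converged, so re-running `regularize()` on an
already-regularized peptide still relaxes the structure by a small amount
(of order 0.1 Å RMSD) even though torsions remain exact and the energy
only decreases. Exact coordinate idempotence would require minimizing to
stationarity, far beyond the 500-step protocol; the tests therefore assert
torsion exactness, convergence and bounded drift rather than bitwise
coordinate stability.

## Structure I/O

PDB output follows the v3.3 fixed columns (first MODEL, chain A, methyl
caps as ACE/NME residues, free termini merged into the first/last residue
with standard H1–H3/OXT/HXT names). Coordinates are written with as many
decimal places as the standard 8-column field can hold — five for values
in (−10, 100), falling back to four or three — because three decimals
fundamentally cannot preserve torsions to the package's 0.01° round-trip
contract (rounding error propagates to ~0.03–0.08° worst case). Column
oriented readers parse the field unchanged; parsing is delegated to
`bio3d::read.pdb`, and torsion extraction uses the same atom quadruples as
the builder (verified in the suite against `bio3d::torsion.pdb` as an
independent implementation). Angles whose defining atoms are absent from
a file are reported as `NA`, never fabricated.

QM decks: the Gaussian-style writer emits a `#` route line (method plus
`opt`, nothing, or `NMR=GIAO`), title, `charge multiplicity`, and the
Cartesian block; the GAMESS-style writer emits minimal `$CONTRL`/`$DATA`
groups with C1 symmetry. The method defaults to the semi-empirical PM6
when none is given. Charge is computed from caps and side-chain
protonation states; multiplicity defaults to 1.

## Problem sizes used in the checks

The shipped tests and the acceptance script run on tripeptides (33–55
atoms) — the fragment size this kind of tool targets — with 10⁴ draws per
residue type for distributional checks, 50 random conformers for file
round-trips, and 200 random assignments for torsion round-trips. The
whole suite completes in about a minute on a single core.

## Known limitations

* No non-standard amino acids, D-amino acids, alternative protonation
  states, disulfides or multi-chain molecules.
* The force field has no electrostatics or attraction; energies are only
  meaningful as a clash-relief objective.
* Mixture defaults are conventional, not fitted; figures produced from
  them illustrate the sampler, not protein statistics.
* mmCIF, trajectories and CONECT records are out of scope; only XYZ, PDB,
  Gaussian-style and GAMESS-style outputs are native.
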