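# pepforge

Build, sample and regularize capped peptide models in R.

Quantum-chemistry studies of proteins are usually carried out on small
capped peptide fragments whose geometry must be controlled exactly: every
backbone torsion (φ, ψ, ω) and side-chain torsion (χₙ) set to a prescribed
value, terminal groups chosen to mimic the surrounding chain, and steric
clashes removed *without* disturbing the chosen torsions, because a clashed
starting structure makes SCF convergence and geometry optimization fail.
`pepforge` is a toolkit for exactly that workflow:

* **Building** — peptides of arbitrary sequence are assembled from
  idealized internal-coordinate residue templates by Natural Extension
  Reference Frame (NeRF) placement. Default torsions are the extended
  β-strand (φ, ψ, ω) = (−120°, 140°, −180°); side chains start at
  clash-free rotamers. Termini can be methyl caps (acetyl / N-methyl
  amide), charged (−NH₃⁺ / −COO⁻) or neutral (−NH₂ / −COOH).
* **Torsion control** — `set_bb_angles()` / `set_chi_angles()` rotate
  rigid branches about the corresponding bonds, so the measured torsion
  equals the request exactly while every bond length and angle is
  untouched. Angles live in the canonical range [−180°, 180°).
* **Conformational sampling** — continuous von Mises mixture models over
  the Ramachandran basins and side-chain rotamers, with exact joint
  log-likelihoods and a seedable sampler (`set_seed()`, `get_sample()`,
  `sample_bb_angles()`, `sample_chi_angles()`; backbone-dependent rotamer
  weighting by default).
* **Regularization** — `regularize()` alternates short restrained
  conjugate-gradient minimizations of a repulsive force field with exact
  torsion resets until the minimized structure's torsions self-consistently
  match their targets (below 0.002°), removing clashes while keeping the
  conformation.
* **I/O** — PDB and XYZ files, plus input decks for quantum-chemistry
  programs (Gaussian-style `.com`, GAMESS-style `.inp`; default method
  PM6). PDB files written by the package round-trip every torsion to
  better than 0.01°, and `read_pdb()` extracts sequences and torsions from
  existing structures.

A command-line front end (`exec/pepforge`, subcommands `build`, `scan`,
`sample`, `regularize`, `qm-input`, `pdb-info`) wraps the same functions
for shell pipelines.

## Worked example

```r
library(pepforge)

pep <- build_peptide("GLG")              # glycine-leucine-glycine, methyl caps
pep <- set_bb_angles(pep, 2, c(-60, -30))
pep <- set_chi_angles(pep, 2, c(180, 60))
pep
#> Peptide GLG (3 residues, 45 atoms; nterm=methyl, cterm=methyl)
#>   1 GLY  phi=-120.00 psi= 140.00 omega=-180.00
#>   2 LEU  phi= -60.00 psi= -30.00 omega=-180.00  chi=-180.00, 60.00
#>   3 GLY  phi=-120.00 psi= 140.00 omega=-180.00

res <- regularize(pep)                   # relax bonds/angles, keep torsions
res
#> OptimizationResult: E = 4.013648 kcal/mol after 300 steps (converged)
#>   last dE = 0.000266 kcal/mol, max torsion deviation = 0.000472 deg

write_pdb(res$peptide, "glg.pdb")
write_qm_input(res$peptide, qm_job("opt", method = "B3LYP/6-31G(d)"),
               "gaussian", "glg.com")
```

The printed torsions are re-measured from the Cartesian coordinates, so
the leucine row confirms that the requested values were applied exactly
(180° reads back as the canonical −180°). The `regularize()` line reports
the force-field energy after clash relief and the largest deviation of any
restrained torsion from its target just before the final exact reset —
the self-consistency measure of the procedure.

Sampling a realistic conformation instead of setting one:

```r
set_seed(42)
s <- get_sample("L")   # a leucine draw without building a peptide
str(s)
#> List of 3
#>  $ chi: num [1:2] -45.4 178.1
#>  $ bb : num [1:2] 83.9 48.3
#>  $ ll : num -2.63
```

`ll` is the exact log joint density of the returned angles under the
sampling model. The same draw applied to a peptide:
`sample_bb_angles(pep, 2)` followed by `sample_chi_angles(pep, 2)`.

From the shell:

```sh
pepforge build --seq GLG --sample --seed 42 --regularize --out glg.pdb
pepforge scan --seq GLG --res 2 --torsion psi --start 100 --step 20 \
  --count 10 --out scan.xyz    # scan_0.xyz ... scan_9.xyz
```

## Notes and limitations

* The shipped energy model is a deliberately simple repulsive force field
  (harmonic bonds/angles at template values, small 3-fold torsion terms,
  r⁻¹² sterics). It is designed for clash relief under torsion restraints,
  not for conformational energetics; see the methods vignette
  (`vignettes/peptide-models.Rmd`) for the model, its parameters and the
  reasoning behind them.
* The sampling mixtures are conventional, replaceable defaults placed at
  the standard Ramachandran/rotamer positions, not densities fitted to
  experimental structures.
* Proline's ring is template-fixed: its φ is built near −65° and cannot be
  set, and it exposes no controllable χ angles.
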