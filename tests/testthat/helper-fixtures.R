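# shared fixtures, built in code at test time

# a peptide with uniformly random controllable torsions
random_conformer <- function(sequence = "GLG") {
  pep <- build_peptide(sequence)
  for (i in seq_along(pep$residues)) {
    bb <- get_bb_angles(pep, i)
    if (!anyNA(bb) && pep$residues[i] != "P") {
      pep <- set_bb_angles(pep, i, runif(3, -180, 180))
    }
    nchi <- length(get_chi_angles(pep, i))
    if (nchi) pep <- set_chi_angles(pep, i, runif(nchi, -180, 180))
  }
  pep
}

# methyl-capped Trp-Asp-Gly conformer whose backbone torsions push the
# C-terminal cap amide hydrogen onto the residue-1 carbonyl oxygen
clash_fixture <- function() {
  pep <- build_peptide("WDG")
  pep <- set_bb_angles(pep, 1, c(111, -152))
  pep <- set_bb_angles(pep, 2, c(-11, -13))
  set_bb_angles(pep, 3, c(-124, 21))
}

# minimum distance over nonbonded (topological separation >= 3) H...O pairs
min_nonbonded_HO <- function(pep) {
  model <- pepforge:::.energy_model(pep)
  el <- pep$atoms$element
  p <- model$nb_pairs
  ho <- p[(el[p[, 1]] == "H" & el[p[, 2]] == "O") |
          (el[p[, 1]] == "O" & el[p[, 2]] == "H"), , drop = FALSE]
  min(sqrt(rowSums((pep$coords[ho[, 1], ] - pep$coords[ho[, 2], ])^2)))
}

# serial of a named atom (unit 0 = N-cap, 1..n residues, n+1 = C-cap)
atom_serial <- function(pep, unit, name) pep$umap[[unit + 1]][[name]]

# chi-square goodness of fit of samples against a 2-D mixture on a coarse
# torus grid; expected bin masses by 1-degree quadrature of the density
chisq_stat_2d <- function(model, draws, nbins = 6) {
  breaks <- seq(-180, 180, length.out = nbins + 1)
  g <- seq(-179.5, 179.5, by = 1)
  dens <- matrix(0, length(g), length(g))
  for (j in seq_along(model$weights)) {
    d1 <- exp(pepforge:::.lvm(g, model$means[j, 1], model$kappas[j, 1]))
    d2 <- exp(pepforge:::.lvm(g, model$means[j, 2], model$kappas[j, 2]))
    dens <- dens + model$weights[j] * outer(d1, d2)
  }
  cell <- findInterval(g, breaks, rightmost.closed = TRUE)
  p <- t(rowsum(t(rowsum(dens, cell)), cell)) # phi bins x psi bins masses
  p <- p / sum(p)
  o <- table(factor(findInterval(draws[, 1], breaks, rightmost.closed = TRUE),
                    levels = 1:nbins),
             factor(findInterval(draws[, 2], breaks, rightmost.closed = TRUE),
                    levels = 1:nbins))
  n <- nrow(draws)
  e <- n * p
  # Cochran's rule: pool cells with expected count < 5 into one class
  big <- e >= 5
  stat <- sum((o[big] - e[big])^2 / e[big])
  df <- sum(big) - 1
  if (any(!big)) {
    stat <- stat + (sum(o[!big]) - sum(e[!big]))^2 / sum(e[!big])
    df <- df + 1
  }
  list(stat = stat, df = df)
}
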