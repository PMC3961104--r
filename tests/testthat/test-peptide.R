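test_that("a fresh build sits at the extended-strand default torsions", {
  pep <- build_peptide("GLG")
  for (i in 1:3) {
    expect_equal(unname(get_bb_angles(pep, i)), c(-120, 140, -180),
                 tolerance = 1e-9)
  }
  expect_equal(nrow(pep$atoms), length(unique(pep$atoms$serial)))
  # sequence is case-insensitive
  pep2 <- build_peptide("glg")
  expect_equal(pep2$sequence, "GLG")
  expect_equal(pep2$coords, pep$coords)
})

test_that("invalid sequences and caps are rejected with position info", {
  expect_error(build_peptide("G?G"), "position 2")
  expect_error(build_peptide("GLB"), "'B' at position 3")
  expect_error(build_peptide(""), "non-empty")
  expect_error(build_peptide("GLG", nterm = "acetylated"), "unknown cap kind")
})

test_that("the worked torsion assignments are reproduced exactly", {
  pep <- build_peptide("GLG")
  pep <- set_bb_angles(pep, 2, c(-60.0, -30.0))
  expect_equal(unname(get_bb_angles(pep, 2)), c(-60, -30, -180),
               tolerance = 1e-9)
  pep <- set_chi_angles(pep, 2, c(180.0, 60.0))
  chi <- unname(get_chi_angles(pep, 2))
  expect_equal(abs(chi[1]), 180, tolerance = 1e-9)  # 180 wraps to -180
  expect_equal(chi[2], 60, tolerance = 1e-9)
  # out-of-range values wrap canonically
  pep <- set_bb_angles(pep, 2, c(-120, 280))
  expect_equal(unname(get_bb_angles(pep, 2)[2]), -80, tolerance = 1e-9)
})

test_that("argument errors are caught", {
  pep <- build_peptide("GLG")
  expect_error(set_bb_angles(pep, 4, c(0, 0)), "out of range")
  expect_error(set_bb_angles(pep, 0, c(0, 0)), "out of range")
  expect_error(set_bb_angles(pep, 2, c(0)), "phi, psi")
  expect_error(set_chi_angles(pep, 2, 180), "2 chi")
  expect_error(set_chi_angles(build_peptide("GGG"), 2, 10), "0 chi")
  expect_silent(set_chi_angles(build_peptide("GGG"), 2, numeric(0)))
  expect_equal(length(get_chi_angles(build_peptide("GGG"), 2)), 0)
})

test_that("set-then-get round-trips 200 random torsion assignments", {
  set.seed(101)
  pep <- build_peptide("KWT")
  worst <- 0
  for (k in 1:200) {
    i <- sample(3, 1)
    bb <- runif(3, -180, 180)
    pep <- set_bb_angles(pep, i, bb)
    worst <- max(worst, abs(wrap_angle(get_bb_angles(pep, i) - bb)))
    nchi <- length(get_chi_angles(pep, i))
    if (nchi) {
      chi <- runif(nchi, -180, 180)
      pep <- set_chi_angles(pep, i, chi)
      worst <- max(worst, abs(wrap_angle(get_chi_angles(pep, i) - chi)))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("side-chain moves leave every backbone torsion untouched", {
  pep <- build_peptide("ILE")
  before <- lapply(1:3, function(i) get_bb_angles(pep, i))
  pep <- set_chi_angles(pep, 2, c(77, -132))
  after <- lapply(1:3, function(i) get_bb_angles(pep, i))
  for (i in 1:3) expect_equal(after[[i]], before[[i]], tolerance = 1e-9)
  # and backbone moves leave other residues' torsions untouched
  chi_before <- get_chi_angles(pep, 2)
  pep <- set_bb_angles(pep, 1, c(-57, -47))
  pep <- set_bb_angles(pep, 3, c(65, 30))
  expect_equal(get_chi_angles(pep, 2), chi_before, tolerance = 1e-9)
  expect_lt(max(abs(wrap_angle(get_bb_angles(pep, 2) - c(-120, 140, -180)))),
            1e-9)
})

test_that("a 10-step psi scan wraps through the canonical range", {
  pep <- build_peptide("GLG")
  got <- numeric(10)
  for (i in 0:9) {
    pep <- set_bb_angles(pep, 2, c(-120, 100 + 20 * i))
    got[i + 1] <- get_bb_angles(pep, 2)[["psi"]]
  }
  expect_equal(got, c(100, 120, 140, 160, -180, -160, -140, -120, -100, -80),
               tolerance = 1e-9)
})

test_that("torsion moves are rigid: no bond length or angle changes", {
  pep <- build_peptide("QYS")
  model <- pepforge:::.energy_model(pep)
  blen <- function(p) sqrt(rowSums((p$coords[p$bonds[, 1], ] -
                                      p$coords[p$bonds[, 2], ])^2))
  bang <- function(p) {
    u <- p$coords[model$angles[, 1], ] - p$coords[model$angles[, 2], ]
    v <- p$coords[model$angles[, 3], ] - p$coords[model$angles[, 2], ]
    acos(pmax(-1, pmin(1, rowSums(u * v) /
                         sqrt(rowSums(u^2) * rowSums(v^2)))))
  }
  l0 <- blen(pep); a0 <- bang(pep)
  set.seed(5)
  for (k in 1:10) {
    pep <- set_bb_angles(pep, sample(3, 1), runif(3, -180, 180))
    pep <- set_chi_angles(pep, 2, runif(2, -180, 180))
  }
  expect_lt(max(abs(blen(pep) - l0)), 1e-9)
  expect_lt(max(abs(bang(pep) - a0)), 1e-9)
})

test_that("cap styles control the terminal chemistry and torsion visibility", {
  pep <- build_peptide("GLG", nterm = "charged", cterm = "neutral")
  nm <- pep$atoms$name[pep$atoms$res_index == 0]
  expect_setequal(nm, c("H1", "H2", "H3"))               # -NH3+
  cm <- pep$atoms$name[pep$atoms$res_index == 4]
  expect_setequal(cm, c("OXT", "HXT"))                   # -COOH
  # no preceding C: phi and omega of residue 1 are undefined
  expect_true(is.na(get_bb_angles(pep, 1)[["phi"]]))
  expect_true(is.na(get_bb_angles(pep, 1)[["omega"]]))
  expect_error(set_bb_angles(pep, 1, c(-60, -30)), "undefined")
  # psi of the last residue is measured through OXT and stays settable
  pep <- set_bb_angles(pep, 3, c(-70, 155))
  expect_equal(unname(get_bb_angles(pep, 3)[1:2]), c(-70, 155),
               tolerance = 1e-9)
  expect_equal(formal_charge(pep), 1)
  expect_equal(formal_charge(build_peptide("GLG")), 0)
  expect_equal(formal_charge(build_peptide("DKR", "charged", "charged")), 1)
})

test_that("proline is ring-locked: fixed phi, no controllable chi", {
  pep <- build_peptide("GPG")
  expect_equal(unname(get_bb_angles(pep, 2)), c(-65, 140, -180),
               tolerance = 1e-9)
  expect_error(set_bb_angles(pep, 2, c(-60, -30)), "ring")
  expect_error(set_chi_angles(pep, 2, c(30)), "0 chi")
  expect_equal(length(get_chi_angles(pep, 2)), 0)
  # psi and the preceding omega remain controllable
  pep <- set_bb_angles(pep, 1, c(-80, 70))
  k <- pepforge:::.torsion_row(pep, 2, "psi")
  pep <- pepforge:::.apply_torsion(pep, k, -40)
  expect_equal(unname(get_bb_angles(pep, 2)[2]), -40, tolerance = 1e-9)
  expect_error(build_peptide("PGG", nterm = "charged"), "methyl")
})
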