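test_that("PDB write/read round-trips residues, coordinates and torsions", {
  pep <- build_peptide("GLG")
  pep <- set_bb_angles(pep, 2, c(-60, -30))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(pep, f)
  m <- read_pdb(f)
  expect_length(m$aa_idx, 3)
  expect_length(m$groups, 5)  # ACE + 3 residues + NME
  expect_equal(vapply(1:3, function(i) pdb_get_resname(m, i), ""),
               c("GLY", "LEU", "GLY"))
  expect_lt(max(abs(wrap_angle(pdb_get_bb_angles(m, 2) - c(-60, -30, -180)))),
            1e-2)
  # coordinates survive the fixed-width format to better than 1e-3 A
  at <- bio3d::read.pdb(f, verbose = FALSE)$atom
  expect_lt(max(abs(cbind(at$x, at$y, at$z) - pep$coords)), 1e-3)
  expect_length(pdb_get_chi_angles(m, 1), 0)  # glycine
  expect_error(pdb_get_resname(m, 9), "out of range")
})

test_that("torsion extraction matches bio3d's independent implementation", {
  set.seed(21)
  pep <- random_conformer("TRW")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(pep, f)
  m <- read_pdb(f)
  tp <- bio3d::torsion.pdb(bio3d::read.pdb(f, verbose = FALSE))
  # bio3d rows: ACE, residues 1..3, NME; phi/psi defined for rows 2..4
  for (i in 1:3) {
    bb <- pdb_get_bb_angles(m, i)
    expect_equal(unname(bb[["phi"]]), tp$phi[i + 1], tolerance = 1e-4)
    expect_equal(unname(bb[["psi"]]), tp$psi[i + 1], tolerance = 1e-4)
  }
  chi1 <- pdb_get_chi_angles(m, 2)[1]
  expect_equal(unname(chi1), tp$chi1[3], tolerance = 1e-4)
})

test_that("50 random conformers round-trip every torsion to 0.01 degrees", {
  set.seed(1)
  f <- withr::local_tempfile(fileext = ".pdb")
  worst <- 0
  alphabet <- setdiff(names(pepforge:::.aa1to3), "P")
  for (k in 1:50) {
    seqs <- paste(sample(alphabet, 3, replace = TRUE), collapse = "")
    pep <- random_conformer(seqs)
    write_pdb(pep, f)
    m <- read_pdb(f)
    for (i in 1:3) {
      worst <- max(worst, abs(wrap_angle(pdb_get_bb_angles(m, i) -
                                           get_bb_angles(pep, i))), na.rm = TRUE)
      chi <- pdb_get_chi_angles(m, i)
      if (length(chi)) {
        worst <- max(worst, abs(wrap_angle(chi - get_chi_angles(pep, i))))
      }
    }
  }
  expect_lt(worst, 0.01)
})

test_that("PDB records obey the v3.3 fixed columns", {
  pep <- build_peptide("GA", nterm = "charged", cterm = "neutral")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(pep, f)
  lines <- readLines(f)
  atom <- grep("^ATOM", lines, value = TRUE)
  expect_true(all(nchar(atom) == 78))
  expect_true(all(substr(atom, 1, 6) == "ATOM  "))
  expect_equal(as.integer(substr(atom, 7, 11)), seq_along(atom))
  expect_true(all(substr(atom, 18, 20) %in% c("GLY", "ALA")))
  expect_true(all(substr(atom, 22, 22) == "A"))
  expect_false(anyNA(suppressWarnings(as.numeric(substr(atom, 31, 38)))))
  expect_false(anyNA(suppressWarnings(as.numeric(substr(atom, 39, 46)))))
  expect_false(anyNA(suppressWarnings(as.numeric(substr(atom, 47, 54)))))
  expect_true(all(substr(atom, 55, 60) == "  1.00"))
  expect_true(all(substr(atom, 61, 66) == "  0.00"))
  expect_true(all(trimws(substr(atom, 77, 78)) %in% c("H", "C", "N", "O", "S")))
  # free termini are merged into the first/last residue
  expect_true(any(grepl(" H1 ", atom)))
  expect_true(any(grepl("OXT", atom)))
  expect_equal(lines[length(lines)], "END")
  expect_true(any(startsWith(lines, "TER")))
})

test_that("the first residue of an uncapped chain has no phi", {
  # minimal hand-written three-residue fragment without caps
  f <- withr::local_tempfile(fileext = ".pdb")
  pep <- build_peptide("AGA", nterm = "charged", cterm = "charged")
  write_pdb(pep, f)
  m <- read_pdb(f)
  expect_true(is.na(pdb_get_bb_angles(m, 1)[["phi"]]))
  expect_true(is.na(pdb_get_bb_angles(m, 1)[["omega"]]))
  expect_false(is.na(pdb_get_bb_angles(m, 3)[["psi"]]))  # via OXT
})

test_that("files without amino acids are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1      10.00000 10.00000 10.00000  1.00  0.00           O",
    "END"), f)
  expect_error(read_pdb(f), "no amino acid")
  expect_error(read_pdb(tempfile()), "not found")
})

test_that("XYZ output carries the atom count and sequence", {
  pep <- build_peptide("GGG")
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(pep, f)
  lines <- readLines(f)
  expect_equal(as.integer(lines[1]), nrow(pep$atoms))
  expect_match(lines[2], "GGG")
  expect_length(lines, nrow(pep$atoms) + 2)
  fields <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  expect_length(fields, 4)
  expect_match(fields[2], "\\.[0-9]{6,}")  # at least 6 decimals
})

test_that("Gaussian decks carry the route, charge and geometry sections", {
  pep <- build_peptide("GAG")
  f <- withr::local_tempfile(fileext = ".com")
  write_qm_input(pep, qm_job("opt", method = "B3LYP/6-31G(d)"), "gaussian", f)
  lines <- readLines(f)
  expect_match(lines[1], "^# B3LYP/6-31G\\(d\\) opt$")
  expect_equal(lines[2], "")
  expect_equal(lines[4], "")
  expect_equal(lines[5], "0 1")
  expect_length(lines, 5 + nrow(pep$atoms) + 1)
  expect_equal(lines[length(lines)], "")
  # defaults: PM6, charge from caps and side chains
  write_qm_input(pep, qm_job("opt"), "gaussian", f)
  expect_match(readLines(f)[1], "^# PM6 opt$")
  write_qm_input(pep, qm_job("energy"), "gaussian", f)
  expect_match(readLines(f)[1], "^# PM6$")
  write_qm_input(pep, qm_job("nmr"), "gaussian", f)
  expect_match(readLines(f)[1], "NMR")
  pk <- build_peptide("GKG", nterm = "charged", cterm = "methyl")
  write_qm_input(pk, qm_job("opt"), "gaussian", f)
  expect_equal(readLines(f)[5], "2 1")
})

test_that("GAMESS decks carry CONTRL and DATA groups", {
  pep <- build_peptide("GAG")
  f <- withr::local_tempfile(fileext = ".inp")
  write_qm_input(pep, qm_job("opt"), "gamess", f)
  lines <- readLines(f)
  expect_match(lines[1], "\\$CONTRL .*RUNTYP=OPTIMIZE .*ICHARG=0 MULT=1")
  expect_equal(lines[2], " $DATA")
  expect_equal(lines[4], "C1")
  expect_match(lines[5], "^C *6\\.0")  # acetyl methyl carbon comes first
  expect_equal(lines[length(lines)], " $END")
})

test_that("atom counts agree between memory, XYZ and PDB", {
  pep <- build_peptide("WLS")
  fx <- withr::local_tempfile(fileext = ".xyz")
  fp <- withr::local_tempfile(fileext = ".pdb")
  write_xyz(pep, fx); write_pdb(pep, fp)
  expect_equal(as.integer(readLines(fx)[1]), nrow(pep$atoms))
  expect_equal(sum(startsWith(readLines(fp), "ATOM")), nrow(pep$atoms))
  # every written file ends in a newline
  for (f in c(fx, fp)) {
    raw <- readBin(f, "raw", file.info(f)$size)
    expect_equal(tail(raw, 1), as.raw(10))
  }
})
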