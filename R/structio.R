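# Structure file I/O: PDB writing/reading (reading is delegated to bio3d)
# with torsion extraction, XYZ output, and input decks for quantum chemistry
# programs (Gaussian-style .com, GAMESS-style .inp).
#
# PDB dialect: v3.3 fixed columns, first MODEL, altloc 'A' (or blank)
# preferred, one chain (the first, by default). Methyl caps are written as
# ACE/NME residues; charged/neutral termini are written as part of the
# first/last residue (standard PDB practice: H1..H3, OXT, HXT). Coordinates
# are written with as many decimals as the standard 8-column field holds
# (5 for values in (-10, 100), falling back to 4 or 3) so that torsions
# survive a write/read round trip to well under 0.01 degrees; column-based
# readers parse the fields unchanged.

.atomic_number <- c(H = 1, C = 6, N = 7, O = 8, S = 16)

# file residue bookkeeping: returns list(resno, resname) per atom
.pdb_residue_map <- function(pep) {
  n <- length(pep$residues)
  ri <- pep$atoms$res_index
  resname <- character(nrow(pep$atoms))
  resno <- integer(nrow(pep$atoms))
  shift <- if (pep$nterm == "methyl") 1L else 0L
  for (a in seq_len(nrow(pep$atoms))) {
    u <- ri[a]
    if (u == 0L) {
      if (pep$nterm == "methyl") { resname[a] <- "ACE"; resno[a] <- 1L }
      else { resname[a] <- .aa1to3[[pep$residues[1L]]]; resno[a] <- 1L }
    } else if (u == n + 1L) {
      if (pep$cterm == "methyl") { resname[a] <- "NME"; resno[a] <- n + shift + 1L }
      else { resname[a] <- .aa1to3[[pep$residues[n]]]; resno[a] <- n + shift }
    } else {
      resname[a] <- .aa1to3[[pep$residues[u]]]; resno[a] <- u + shift
    }
  }
  list(resno = resno, resname = resname)
}

# format one coordinate into the fixed 8-column PDB field at the highest
# decimal precision that fits
.fmt_coord <- function(x) {
  vapply(x, function(v) {
    for (fmt in c("%8.5f", "%8.4f", "%8.3f")) {
      s <- sprintf(fmt, v)
      if (nchar(s) == 8L) return(s)
    }
    stop("coordinate out of PDB field range: ", v, call. = FALSE)
  }, "")
}

.pdb_atom_field <- function(name) {
  # names of up to 3 characters start in column 14; 4-character names fill
  # columns 13-16
  if (nchar(name) >= 4L) substr(name, 1L, 4L) else sprintf(" %-3s", name)
}

#' Write the peptide to a PDB file
#'
#' @param pep a `Peptide`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(pep, path) {
  rmap <- .pdb_residue_map(pep)
  lines <- character(nrow(pep$atoms))
  for (a in seq_len(nrow(pep$atoms))) {
    lines[a] <- sprintf(
      "ATOM  %5d %s %3s %1s%4d    %s%s%s%6.2f%6.2f          %2s",
      a, .pdb_atom_field(pep$atoms$name[a]), rmap$resname[a], "A",
      rmap$resno[a], .fmt_coord(pep$coords[a, 1L]), .fmt_coord(pep$coords[a, 2L]),
      .fmt_coord(pep$coords[a, 3L]), 1, 0, pep$atoms$element[a])
  }
  last <- nrow(pep$atoms)
  ter <- sprintf("TER   %5d      %3s %1s%4d", last + 1L, rmap$resname[last],
                 "A", rmap$resno[last])
  writeLines(c(lines, ter, "END"), path)
  invisible(path)
}

#' Write the peptide to an XYZ file
#'
#' Line 1 is the atom count, line 2 a comment containing the sequence,
#' followed by `element x y z` records.
#'
#' @param pep a `Peptide`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_xyz <- function(pep, path) {
  lines <- c(
    sprintf("%d", nrow(pep$atoms)),
    sprintf("peptide %s (nterm=%s, cterm=%s)", pep$sequence, pep$nterm, pep$cterm),
    sprintf("%-2s %15.8f %15.8f %15.8f", pep$atoms$element,
            pep$coords[, 1L], pep$coords[, 2L], pep$coords[, 3L]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PDB file
#'
#' Parses the ATOM/HETATM records of the first MODEL via [bio3d::read.pdb()],
#' keeping one chain (the first, unless `chain` is given) and resolving
#' alternate locations in favour of 'A'/blank. Amino-acid residues are
#' indexed 1..n in order of appearance; ACE/NME capping groups are retained
#' as flanking groups but are not counted in the residue indexing.
#'
#' @param path path to a PDB-format file.
#' @param chain optional chain identifier; default: the first chain present.
#' @return a `PdbModel`: list of residue groups with atom names and
#'   coordinates.
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- try(suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                              verbose = FALSE)), silent = TRUE)
  if (inherits(pdb, "try-error")) {
    stop("could not parse PDB file: ", path, call. = FALSE)
  }
  at <- pdb$atom
  if (!nrow(at)) stop("no ATOM records in ", path, call. = FALSE)
  ch <- if (is.null(chain)) at$chain[1L] else chain
  if (!is.na(ch)) at <- at[at$chain == ch | is.na(at$chain), , drop = FALSE]
  key <- paste(at$resno, at$insert)
  groups <- list()
  for (k in unique(key)) {
    rows <- at[key == k, , drop = FALSE]
    groups[[length(groups) + 1L]] <- list(
      resname = rows$resid[1L], resno = rows$resno[1L],
      atoms = stats::setNames(
        lapply(seq_len(nrow(rows)), function(r) c(rows$x[r], rows$y[r], rows$z[r])),
        rows$elety))
  }
  aa_idx <- which(vapply(groups, function(g) g$resname %in% names(.aa3to1), TRUE))
  if (!length(aa_idx)) stop("no amino acid residues in ", path, call. = FALSE)
  structure(list(groups = groups, aa_idx = aa_idx, source = path),
            class = "PdbModel")
}

.pdb_group <- function(model, res) {
  if (!is.numeric(res) || length(res) != 1L || res < 1L ||
      res > length(model$aa_idx)) {
    stop("residue index out of range: ", res, " (model has ",
         length(model$aa_idx), " amino-acid residues)", call. = FALSE)
  }
  model$groups[[model$aa_idx[as.integer(res)]]]
}

#' Residue name at an index of a PDB model
#'
#' @param model a `PdbModel` from [read_pdb()].
#' @param res 1-based amino-acid residue index.
#' @return the 3-letter residue name.
#' @export
pdb_get_resname <- function(model, res) .pdb_group(model, res)$resname

.pdb_atom_xyz <- function(group, name) {
  if (is.null(group) || is.null(group$atoms[[name]])) return(NULL)
  group$atoms[[name]]
}

#' Backbone torsions of a residue in a PDB model
#'
#' Measures phi, psi and the preceding omega with the same atom quadruples
#' as the peptide builder. Methyl cap atoms (ACE C/CH3, NME N) and a free
#' carboxyl OXT substitute for missing neighbours; an angle whose defining
#' atoms are absent is reported as `NA`.
#'
#' @param model a `PdbModel`.
#' @param res 1-based amino-acid residue index.
#' @return `c(phi, psi, omega)` in degrees (possibly `NA`).
#' @export
pdb_get_bb_angles <- function(model, res) {
  g <- .pdb_group(model, res)
  gi <- model$aa_idx[as.integer(res)]
  prev <- if (gi > 1L) model$groups[[gi - 1L]] else NULL
  nxt <- if (gi < length(model$groups)) model$groups[[gi + 1L]] else NULL
  # cap substitutes
  pC <- .pdb_atom_xyz(prev, "C")
  pCA <- if (!is.null(prev) && prev$resname == "ACE") {
    p <- .pdb_atom_xyz(prev, "CH3")
    if (is.null(p)) .pdb_atom_xyz(prev, "CA") else p
  } else .pdb_atom_xyz(prev, "CA")
  nN <- .pdb_atom_xyz(nxt, "N")
  if (is.null(nN)) nN <- .pdb_atom_xyz(g, "OXT")
  N <- .pdb_atom_xyz(g, "N"); CA <- .pdb_atom_xyz(g, "CA"); C <- .pdb_atom_xyz(g, "C")
  dih <- function(a, b, c, d) {
    if (is.null(a) || is.null(b) || is.null(c) || is.null(d)) return(NA_real_)
    measure_dihedral(a, b, c, d)
  }
  c(phi = dih(pC, N, CA, C), psi = dih(N, CA, C, nN), omega = dih(pCA, pC, N, CA))
}

#' Side-chain torsions of a residue in a PDB model
#'
#' Uses the standard IUPAC chi quadruples from the residue templates. A chi
#' whose defining atoms are missing from the file is `NA`; residues without
#' controllable side-chain torsions give an empty vector.
#'
#' @param model a `PdbModel`.
#' @param res 1-based amino-acid residue index.
#' @return numeric vector of chi angles in degrees.
#' @export
pdb_get_chi_angles <- function(model, res) {
  g <- .pdb_group(model, res)
  code1 <- .aa3to1[[g$resname]]
  tmpl <- get_template(code1)
  out <- numeric(0)
  for (k in seq_along(tmpl$chi_defs)) {
    quad <- lapply(tmpl$chi_defs[[k]], function(nm) .pdb_atom_xyz(g, nm))
    out[k] <- if (any(vapply(quad, is.null, TRUE))) NA_real_ else
      measure_dihedral(quad[[1L]], quad[[2L]], quad[[3L]], quad[[4L]])
  }
  if (length(out)) names(out) <- names(tmpl$chi_defs)
  out
}

#' Describe a quantum-chemistry job
#'
#' @param job one of `"opt"` (geometry optimization), `"energy"`
#'   (single point), `"nmr"` (NMR shielding).
#' @param method method/basis string, e.g. `"B3LYP/6-31G(d)"`; defaults to
#'   the semi-empirical `"PM6"`.
#' @param charge total charge; default: computed from the cap kinds and
#'   side-chain protonation states via [formal_charge()].
#' @param multiplicity spin multiplicity (default 1).
#' @param header optional character vector of extra header lines (e.g.
#'   Gaussian `%mem` directives), written verbatim before the route line.
#' @return a `QmJobSpec`.
#' @export
qm_job <- function(job = c("opt", "energy", "nmr"), method = NULL,
                   charge = NULL, multiplicity = 1, header = character()) {
  job <- match.arg(job)
  if (is.null(method) || !nzchar(method)) method <- "PM6"
  if (multiplicity < 1) stop("multiplicity must be >= 1", call. = FALSE)
  structure(list(job = job, method = method, charge = charge,
                 multiplicity = as.integer(multiplicity), header = header),
            class = "QmJobSpec")
}

#' Write a quantum-chemistry input deck
#'
#' Gaussian dialect: optional header lines, a `#` route line with the method
#' and job keyword, title and charge/multiplicity sections, then Cartesian
#' coordinates. GAMESS dialect: minimal `$CONTRL` and `$DATA` groups with C1
#' symmetry. The default method is PM6 when none is set.
#'
#' @param pep a `Peptide`.
#' @param spec a `QmJobSpec` from [qm_job()]; default: a PM6 geometry
#'   optimization.
#' @param dialect `"gaussian"` or `"gamess"`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @examples
#' pep <- build_peptide("GAG")
#' f <- tempfile(fileext = ".com")
#' write_qm_input(pep, qm_job("opt", method = "B3LYP/6-31G(d)"), "gaussian", f)
#' @export
write_qm_input <- function(pep, spec = qm_job("opt"),
                           dialect = c("gaussian", "gamess"), path) {
  dialect <- match.arg(dialect)
  if (!inherits(spec, "QmJobSpec")) stop("spec must be a QmJobSpec", call. = FALSE)
  charge <- if (is.null(spec$charge)) formal_charge(pep) else as.integer(spec$charge)
  title <- sprintf("pepforge peptide %s (%s job)", pep$sequence, spec$job)
  if (dialect == "gaussian") {
    keyword <- switch(spec$job, opt = " opt", energy = "", nmr = " NMR=GIAO")
    lines <- c(spec$header,
               sprintf("# %s%s", spec$method, keyword),
               "", title, "",
               sprintf("%d %d", charge, spec$multiplicity),
               sprintf("%-2s %15.8f %15.8f %15.8f", pep$atoms$element,
                       pep$coords[, 1L], pep$coords[, 2L], pep$coords[, 3L]),
               "")
  } else {
    runtyp <- switch(spec$job, opt = "OPTIMIZE", energy = "ENERGY", nmr = "NMR")
    lines <- c(sprintf(" $CONTRL SCFTYP=RHF RUNTYP=%s ICHARG=%d MULT=%d $END",
                       runtyp, charge, spec$multiplicity),
               " $DATA", title, "C1",
               sprintf("%-2s %4.1f %15.8f %15.8f %15.8f", pep$atoms$element,
                       .atomic_number[pep$atoms$element],
                       pep$coords[, 1L], pep$coords[, 2L], pep$coords[, 3L]),
               " $END")
  }
  writeLines(lines, path)
  invisible(path)
}
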