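# Idealized residue and cap geometries, shipped as plain-text internal
# coordinate tables under inst/extdata/templates/ (one file per residue or
# cap). Each atom row gives the atom name, element, three reference atoms,
# bond length (Angstrom), bond angle (degrees) and a dihedral specification
# that is either an absolute value or an expression in a controllable torsion
# (phi, psi, omega, chi1..chi4, or psi- for the preceding unit's psi).

.aa1to3 <- c(G = "GLY", A = "ALA", S = "SER", C = "CYS", T = "THR", V = "VAL",
             L = "LEU", I = "ILE", M = "MET", P = "PRO", D = "ASP", N = "ASN",
             E = "GLU", Q = "GLN", K = "LYS", R = "ARG", H = "HIS", F = "PHE",
             Y = "TYR", W = "TRP")
.aa3to1 <- structure(names(.aa1to3), names = .aa1to3)

# side-chain formal charges of the shipped protonation states (pH ~7)
.residue_charge <- c(ASP = -1L, GLU = -1L, LYS = 1L, ARG = 1L)

.template_cache <- new.env(parent = emptyenv())

.template_dir <- function() {
  d <- system.file("extdata", "templates", package = "pepforge")
  if (!nzchar(d)) stop("template data directory not found", call. = FALSE)
  d
}

# parse a "dihedral" field into list(torsion = name or NA, offset = degrees)
.parse_tau <- function(s) {
  if (grepl("^[-+]?[0-9.]+$", s)) {
    return(list(torsion = NA_character_, offset = as.numeric(s)))
  }
  m <- regmatches(s, regexec("^(phi|psi|omega|chi[1-4]|psi-)([+-][0-9.]+)?$", s))[[1]]
  if (length(m) == 0L) stop("unparseable dihedral field: ", s, call. = FALSE)
  off <- if (nzchar(m[3L])) as.numeric(m[3L]) else 0
  list(torsion = m[2L], offset = off)
}

.read_template_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  out <- list(atoms = list(), chi_defs = list(), default_chi = numeric(),
              rings = list())
  for (tk in toks) {
    switch(tk[1L],
      residue = {
        out$code3 <- tk[2L]; out$code1 <- tk[3L]; out$is_cap <- FALSE
      },
      cap = {
        out$kind <- tk[2L]; out$terminus <- tk[3L]; out$code3 <- tk[4L]
        out$is_cap <- TRUE
      },
      chi = {
        out$chi_defs[[tk[2L]]] <- tk[3:6]
      },
      default_chi = {
        out$default_chi <- as.numeric(tk[-1L])
      },
      atom = {
        tau <- .parse_tau(tk[9L])
        out$atoms[[length(out$atoms) + 1L]] <- list(
          name = tk[2L], element = tk[3L],
          ref_a = tk[4L], ref_b = tk[5L], ref_c = tk[6L],
          length = as.numeric(tk[7L]), angle = as.numeric(tk[8L]),
          torsion = tau$torsion, offset = tau$offset)
      },
      ring = {
        out$rings[[length(out$rings) + 1L]] <-
          list(a = tk[2L], b = tk[3L], length = as.numeric(tk[4L]))
      },
      stop("unknown template record: ", tk[1L], call. = FALSE))
  }
  nm <- vapply(out$atoms, `[[`, "", "name")
  for (cd in out$chi_defs) {
    if (!all(cd %in% nm)) {
      stop("chi definition references unknown atom in ", path, call. = FALSE)
    }
  }
  for (a in out$atoms) {
    if (a$length < 0 || a$angle < 0 || a$angle >= 180) {
      stop("invalid internal coordinates for atom ", a$name, " in ", path,
           call. = FALSE)
    }
  }
  out$n_chi <- length(out$chi_defs)
  class(out) <- if (out$is_cap) "CapTemplate" else "ResidueTemplate"
  out
}

#' Retrieve the idealized template for a residue type
#'
#' Templates carry the internal-coordinate geometry (bond lengths, bond
#' angles, dihedral expressions) used to build each residue, the IUPAC
#' chi-angle atom quadruples and the default side-chain torsion values.
#' Proline's pyrrolidine ring is template-fixed, so it exposes no
#' controllable chi angles.
#'
#' @param code a one-letter amino-acid code (case-insensitive).
#' @return an object of class `ResidueTemplate` with fields `code3`, `code1`,
#'   `atoms`, `chi_defs`, `n_chi`, `default_chi`, `rings`.
#' @examples
#' get_template("L")$n_chi # leucine has chi1 and chi2
#' @export
get_template <- function(code) {
  code <- toupper(code)
  if (!is.character(code) || length(code) != 1L || !code %in% names(.aa1to3)) {
    stop("unknown amino-acid code: '", code, "'", call. = FALSE)
  }
  key <- .aa1to3[[code]]
  if (is.null(.template_cache[[key]])) {
    .template_cache[[key]] <-
      .read_template_file(file.path(.template_dir(), paste0(key, ".txt")))
  }
  .template_cache[[key]]
}

#' Retrieve a terminal cap template
#'
#' Methyl caps are an acetyl group (CH3-C(=O)-) at the N-terminus and an
#' N-methyl amide (-NH-CH3) at the C-terminus; `charged`/`neutral` give the
#' free termini -NH3+/-NH2 and -COO-/-COOH. Methyl is the default cap used by
#' [build_peptide()] when no cap keyword is given.
#'
#' @param kind one of `"methyl"`, `"charged"`, `"neutral"`.
#' @param terminus `"N"` or `"C"`.
#' @return an object of class `CapTemplate`.
#' @export
get_cap <- function(kind, terminus) {
  kind <- tolower(kind)
  if (!kind %in% c("methyl", "charged", "neutral")) {
    stop("unknown cap kind: '", kind, "' (expected methyl, charged or neutral)",
         call. = FALSE)
  }
  terminus <- toupper(terminus)
  if (!terminus %in% c("N", "C")) stop("terminus must be 'N' or 'C'", call. = FALSE)
  key <- paste0(if (terminus == "N") "nterm_" else "cterm_", kind)
  if (is.null(.template_cache[[key]])) {
    .template_cache[[key]] <-
      .read_template_file(file.path(.template_dir(), paste0(key, ".txt")))
  }
  .template_cache[[key]]
}
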