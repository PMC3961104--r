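# Assembly of a capped peptide from internal-coordinate templates, and exact
# manipulation of its backbone and side-chain torsion angles by rigid branch
# rotation.
#
# Torsion conventions (atom quadruples):
#   phi(i)   = C(i-1) - N(i) - CA(i) - C(i)
#   psi(i)   = N(i) - CA(i) - C(i) - N(i+1)
#   omega(i) = CA(i-1) - C(i-1) - N(i) - CA(i)   (the peptide bond preceding
#              residue i's N; set_bb_angles(res, c(phi, psi, omega)) controls it)
#   chi_k    = the standard IUPAC side-chain quadruples stored per template.
# Methyl cap heavy atoms substitute for the missing neighbours of terminal
# residues (the acetyl C plays C(0), the N-methyl N plays N(n+1), and a free
# carboxyl's OXT plays N(n+1)). A torsion whose flanking atom does not exist
# for the chosen cap style is undefined: it is reported as NA and cannot be
# set.

.bb_defaults <- c(phi = -120, psi = 140, omega = -180)
# proline's ring-locked phi; the template ring is built for this value
.pro_phi <- -65

#' Build a capped peptide at default torsions
#'
#' Assembles the molecule residue by residue from idealized internal
#' coordinate templates. All backbone torsions start at the extended
#' beta-strand defaults phi = -120, psi = 140, omega = -180 (proline's phi is
#' ring-locked near -65), and side chains start at the clash-free template
#' default chi values.
#'
#' @param sequence one-letter amino-acid string (case-insensitive).
#' @param nterm,cterm cap kinds: `"methyl"` (default), `"charged"`, `"neutral"`.
#' @return an object of class `Peptide`: a list with the atom table
#'   (`$atoms`), coordinates (`$coords`, Angstrom), bond list (`$bonds`),
#'   torsion registry (`$torsions`) and bookkeeping fields.
#' @examples
#' pep <- build_peptide("GLG")
#' get_bb_angles(pep, 2)
#' @export
build_peptide <- function(sequence, nterm = "methyl", cterm = "methyl") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty character string", call. = FALSE)
  }
  seq1 <- toupper(strsplit(sequence, "")[[1]])
  bad <- which(!seq1 %in% names(.aa1to3))
  if (length(bad)) {
    stop(sprintf("invalid amino-acid code '%s' at position %d",
                 strsplit(sequence, "")[[1]][bad[1L]], bad[1L]), call. = FALSE)
  }
  nterm <- tolower(nterm); cterm <- tolower(cterm)
  ncap <- get_cap(nterm, "N")   # validates kind
  ccap <- get_cap(cterm, "C")
  n <- length(seq1)
  tmpl <- lapply(seq1, get_template)
  if (nterm != "methyl" && seq1[1L] == "P") {
    stop("proline at a free (charged/neutral) N-terminus is not supported; ",
         "use a methyl cap", call. = FALSE)
  }

  # ---- collect placement records ------------------------------------------
  # each record: unit (0 = N-cap, 1..n residues, n+1 = C-cap), atom fields,
  # qualified torsion (list(name, res) or NULL), offset
  recs <- list()
  add <- function(unit, a, tor, skip_H = FALSE) {
    for (at in a$atoms) {
      if (skip_H && at$name == "H") next
      q <- NULL
      if (!is.na(at$torsion)) {
        if (at$torsion == "psi-") {
          if (tor$prev_res >= 1L) q <- list(name = "psi", res = tor$prev_res)
          # else: previous unit is the acetyl cap; its in-plane reference atom
          # (the carbonyl O) stands at the trans position, handled as absolute
        } else {
          q <- list(name = at$torsion, res = tor$res)
        }
      }
      recs[[length(recs) + 1L]] <<- list(
        unit = unit, name = at$name, element = at$element,
        ref_a = at$ref_a, ref_b = at$ref_b, ref_c = at$ref_c,
        length = at$length, angle = at$angle,
        q = q, offset = at$offset,
        prev_cap_trans = is.na(at$torsion) == FALSE && at$torsion == "psi-" &&
          tor$prev_res < 1L)
    }
  }

  if (nterm == "methyl") {
    add(0L, ncap, list(res = 0L, prev_res = 0L))
    for (i in seq_len(n)) add(i, tmpl[[i]], list(res = i, prev_res = i - 1L))
  } else {
    add(1L, tmpl[[1L]], list(res = 1L, prev_res = 0L), skip_H = TRUE)
    add(0L, ncap, list(res = 1L, prev_res = 0L))  # refs resolve in residue 1
    for (i in seq_len(n)[-1L]) add(i, tmpl[[i]], list(res = i, prev_res = i - 1L))
  }
  add(n + 1L, ccap, list(res = n + 1L, prev_res = n))

  # ---- torsion start values ------------------------------------------------
  tval <- function(q) {
    if (q$name %in% c("phi", "psi", "omega")) {
      if (q$name == "phi" && seq1[q$res] == "P") return(.pro_phi)
      return(unname(.bb_defaults[q$name]))
    }
    k <- as.integer(sub("chi", "", q$name))
    tmpl[[q$res]]$default_chi[k]
  }

  # ---- sequential NeRF placement ------------------------------------------
  nat <- length(recs)
  coords <- matrix(NA_real_, nat, 3L)
  parent <- integer(nat)
  blen <- numeric(nat)
  # name -> serial maps per unit; the N-cap map for charged/neutral termini
  # aliases residue 1
  umap <- vector("list", n + 2L)
  for (u in seq_along(umap)) umap[[u]] <- list()
  uget <- function(unit, nm) {
    # names prefixed '-' live in the previous unit (unit 0 is the N-cap)
    if (startsWith(nm, "-")) {
      nm <- substring(nm, 2L)
      pu <- if (unit >= 2L) unit - 1L else 0L
      if (unit == 1L && nterm == "methyl") {
        # role map: the acetyl group's atoms stand in for the missing residue 0
        nm <- switch(nm, N = "O", CA = "CH3", C = "C", nm)
      } else if (unit == 1L) {
        return(NA_integer_)  # free N-terminus: no preceding unit
      }
      s <- umap[[pu + 1L]][[nm]]
    } else {
      un <- if (unit == 0L && nterm != "methyl") 1L else unit
      s <- umap[[un + 1L]][[nm]]
    }
    if (is.null(s)) NA_integer_ else s
  }

  for (s in seq_len(nat)) {
    r <- recs[[s]]
    ia <- uget(r$unit, r$ref_a); ib <- uget(r$unit, r$ref_b); ic <- uget(r$unit, r$ref_c)
    if (s == 1L) {
      coords[s, ] <- c(0, 0, 0)
      parent[s] <- 0L
    } else if (s == 2L) {
      coords[s, ] <- c(r$length, 0, 0)
      parent[s] <- 1L; blen[s] <- r$length
    } else if (s == 3L) {
      th <- r$angle * .deg2rad
      org <- coords[ic, ]
      dir <- coords[ib, ] - org
      dir <- dir / .norm3(dir)
      coords[s, ] <- org + r$length * (dir * cos(th) + c(-dir[2L], dir[1L], 0) * sin(th))
      parent[s] <- ic; blen[s] <- r$length
    } else {
      if (any(is.na(c(ia, ib, ic)))) {
        stop("unresolvable reference atoms while placing ", r$name,
             " of unit ", r$unit, call. = FALSE)
      }
      tau <- r$offset
      if (!is.null(r$q)) tau <- tau + tval(r$q)
      if (isTRUE(r$prev_cap_trans)) tau <- tau + 180
      coords[s, ] <- place_atom(coords[ia, ], coords[ib, ], coords[ic, ],
                                r$length, r$angle, tau)
      parent[s] <- ic; blen[s] <- r$length
    }
    umap[[r$unit + 1L]][[r$name]] <- s
  }

  atoms <- data.frame(
    serial = seq_len(nat),
    name = vapply(recs, `[[`, "", "name"),
    element = vapply(recs, `[[`, "", "element"),
    res_index = vapply(recs, `[[`, 0L, "unit"),
    stringsAsFactors = FALSE)

  bonds <- cbind(parent[parent > 0L], which(parent > 0L))
  ref_len <- blen[parent > 0L]
  # ring-closure bonds (proline, aromatic rings)
  ring_units <- c(if (nterm == "methyl") list(list(u = 0L, t = ncap)) else NULL,
                  lapply(seq_len(n), function(i) list(u = i, t = tmpl[[i]])),
                  list(list(u = n + 1L, t = ccap)))
  for (ru in ring_units) {
    for (rg in ru$t$rings) {
      bonds <- rbind(bonds, c(umap[[ru$u + 1L]][[rg$a]], umap[[ru$u + 1L]][[rg$b]]))
      ref_len <- c(ref_len, rg$length)
    }
  }
  colnames(bonds) <- c("i", "j")

  pep <- structure(list(
    sequence = paste(seq1, collapse = ""),
    residues = seq1, nterm = nterm, cterm = cterm,
    atoms = atoms, coords = coords,
    bonds = bonds, bond_ref_length = ref_len,
    umap = umap), class = "Peptide")

  pep$torsions <- .register_torsions(pep, tmpl)
  pep$branches <- .compute_branches(pep)
  pep$torsions$settable <- attr(pep$branches, "settable")

  # bookkeeping invariant: every stored target must equal the measured value
  meas <- vapply(seq_len(nrow(pep$torsions)), function(k) .measure_torsion(pep, k), 0)
  dev <- abs(wrap_angle(meas - pep$torsions$target))
  if (any(dev > 1e-6)) {
    stop("internal template inconsistency: built torsion deviates from target by ",
         format(max(dev)), " degrees", call. = FALSE)
  }
  pep
}

# serial lookup helper: atom `nm` of unit u (residues are 1..n)
.serial <- function(pep, u, nm) {
  s <- pep$umap[[u + 1L]][[nm]]
  if (is.null(s)) NA_integer_ else s
}

.register_torsions <- function(pep, tmpl) {
  n <- length(pep$residues)
  rows <- list()
  addrow <- function(res, name, a, b, c, d, settable) {
    if (any(is.na(c(a, b, c, d)))) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      res = res, name = name, a = a, b = b, c = c, d = d,
      settable = settable, target = NA_real_, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    N <- .serial(pep, i, "N"); CA <- .serial(pep, i, "CA"); C <- .serial(pep, i, "C")
    if (i > 1L) {
      pC <- .serial(pep, i - 1L, "C"); pCA <- .serial(pep, i - 1L, "CA")
    } else if (pep$nterm == "methyl") {
      pC <- .serial(pep, 0L, "C"); pCA <- .serial(pep, 0L, "CH3")
    } else {
      pC <- NA_integer_; pCA <- NA_integer_
    }
    if (i < n) {
      nN <- .serial(pep, i + 1L, "N")
    } else if (pep$cterm == "methyl") {
      nN <- .serial(pep, n + 1L, "N")
    } else {
      nN <- .serial(pep, n + 1L, "OXT")  # free carboxyl: OXT plays N(i+1)
    }
    addrow(i, "phi", pC, N, CA, C, settable = pep$residues[i] != "P")
    addrow(i, "psi", N, CA, C, nN, settable = TRUE)
    addrow(i, "omega", pCA, pC, N, CA, settable = TRUE)
    cds <- tmpl[[i]]$chi_defs
    for (k in seq_along(cds)) {
      qd <- vapply(cds[[k]], function(nm) .serial(pep, i, nm), 0L)
      addrow(i, paste0("chi", k), qd[1L], qd[2L], qd[3L], qd[4L], settable = TRUE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$target <- vapply(seq_len(nrow(tab)), function(k) {
    measure_dihedral(pep$coords[tab$a[k], ], pep$coords[tab$b[k], ],
                     pep$coords[tab$c[k], ], pep$coords[tab$d[k], ])
  }, 0)
  tab
}

.compute_branches <- function(pep) {
  g <- igraph::graph_from_edgelist(pep$bonds, directed = FALSE)
  branches <- vector("list", nrow(pep$torsions))
  for (k in seq_len(nrow(pep$torsions))) {
    if (!pep$torsions$settable[k]) next
    b <- pep$torsions$b[k]; cc <- pep$torsions$c[k]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(b, cc)))
    comp <- igraph::components(g2)$membership
    if (comp[b] == comp[cc]) {
      # bond inside a ring: torsion cannot be rotated rigidly
      pep$torsions$settable[k] <- FALSE
      next
    }
    branches[[k]] <- setdiff(which(comp == comp[cc]), cc)
  }
  attr(branches, "settable") <- pep$torsions$settable
  branches
}

.measure_torsion <- function(pep, k) {
  t <- pep$torsions
  measure_dihedral(pep$coords[t$a[k], ], pep$coords[t$b[k], ],
                   pep$coords[t$c[k], ], pep$coords[t$d[k], ])
}

.torsion_row <- function(pep, res, name) {
  which(pep$torsions$res == res & pep$torsions$name == name)
}

.check_res <- function(pep, res) {
  n <- length(pep$residues)
  if (!is.numeric(res) || length(res) != 1L || res < 1L || res > n || res != round(res)) {
    stop("residue index out of range: ", res, " (peptide has ", n, " residues)",
         call. = FALSE)
  }
  as.integer(res)
}

# rotate a registered torsion to an absolute (canonically wrapped) value
.apply_torsion <- function(pep, k, value) {
  value <- wrap_angle(value)
  t <- pep$torsions
  if (!t$settable[k]) {
    stop(t$name[k], " of residue ", t$res[k],
         " is fixed (ring-closed) and cannot be set", call. = FALSE)
  }
  cur <- .measure_torsion(pep, k)
  delta <- wrap_angle(value - cur)
  if (delta != 0) {
    pep$coords <- rotate_branch(pep$coords, t$b[k], t$c[k],
                                pep$branches[[k]], delta)
  }
  pep$torsions$target[k] <- value
  pep
}

#' Set backbone torsion angles of one residue
#'
#' Rotates the peptide rigidly about the corresponding backbone bonds so that
#' the measured phi and psi (and optionally the preceding omega) of residue
#' `res` equal the requested values exactly. Bond lengths and angles are
#' untouched; all other torsions are unchanged.
#'
#' @param pep a `Peptide`.
#' @param res 1-based residue index.
#' @param angles numeric `c(phi, psi)` or `c(phi, psi, omega)` in degrees.
#' @return the updated `Peptide`.
#' @examples
#' pep <- build_peptide("GLG")
#' pep <- set_bb_angles(pep, 2, c(-60, -30))
#' @export
set_bb_angles <- function(pep, res, angles) {
  res <- .check_res(pep, res)
  if (!is.numeric(angles) || !length(angles) %in% c(2L, 3L)) {
    stop("angles must be c(phi, psi) or c(phi, psi, omega)", call. = FALSE)
  }
  names(angles) <- c("phi", "psi", "omega")[seq_along(angles)]
  for (nm in names(angles)) {
    k <- .torsion_row(pep, res, nm)
    if (length(k) == 0L) {
      stop(nm, " is undefined for residue ", res, " with the '",
           if (nm == "psi") pep$cterm else pep$nterm, "' cap", call. = FALSE)
    }
    pep <- .apply_torsion(pep, k, angles[[nm]])
  }
  pep
}

#' Set side-chain chi torsion angles of one residue
#'
#' @param pep a `Peptide`.
#' @param res 1-based residue index.
#' @param angles numeric vector of chi values in degrees whose length must
#'   equal the residue's number of controllable side-chain torsions (0 for
#'   glycine, alanine and proline: pass `numeric(0)`).
#' @return the updated `Peptide`.
#' @export
set_chi_angles <- function(pep, res, angles) {
  res <- .check_res(pep, res)
  ks <- which(pep$torsions$res == res & grepl("^chi", pep$torsions$name))
  if (length(angles) != length(ks)) {
    stop(sprintf("residue %d (%s) has %d chi angle(s), got %d", res,
                 .aa1to3[[pep$residues[res]]], length(ks), length(angles)),
         call. = FALSE)
  }
  for (j in seq_along(ks)) pep <- .apply_torsion(pep, ks[j], angles[j])
  pep
}

#' Read backbone torsion angles of one residue
#'
#' @param pep a `Peptide`.
#' @param res 1-based residue index.
#' @return `c(phi, psi, omega)` in degrees, measured from the current
#'   Cartesian coordinates; `NA` for an angle undefined under the cap style.
#' @export
get_bb_angles <- function(pep, res) {
  res <- .check_res(pep, res)
  vapply(c("phi", "psi", "omega"), function(nm) {
    k <- .torsion_row(pep, res, nm)
    if (length(k) == 0L) NA_real_ else .measure_torsion(pep, k)
  }, 0)
}

#' Read side-chain torsion angles of one residue
#'
#' @param pep a `Peptide`.
#' @param res 1-based residue index.
#' @return numeric vector of measured chi values (empty for glycine, alanine
#'   and proline).
#' @export
get_chi_angles <- function(pep, res) {
  res <- .check_res(pep, res)
  ks <- which(pep$torsions$res == res & grepl("^chi", pep$torsions$name))
  out <- vapply(ks, function(k) .measure_torsion(pep, k), 0)
  names(out) <- pep$torsions$name[ks]
  out
}

#' Total formal charge of the peptide
#'
#' Sum of the cap contributions (+1 for a charged N-terminus, -1 for a
#' charged C-terminus) and the side-chain formal charges of the shipped
#' protonation states (Asp/Glu -1, Lys/Arg +1, neutral His).
#'
#' @param pep a `Peptide`.
#' @return integer charge.
#' @export
formal_charge <- function(pep) {
  ch <- 0L
  if (pep$nterm == "charged") ch <- ch + 1L
  if (pep$cterm == "charged") ch <- ch - 1L
  ch + sum(.residue_charge[.aa1to3[pep$residues]], na.rm = TRUE)
}

#' @export
print.Peptide <- function(x, ...) {
  cat(sprintf("Peptide %s (%d residue%s, %d atoms; nterm=%s, cterm=%s)\n",
              x$sequence, length(x$residues),
              if (length(x$residues) > 1L) "s" else "", nrow(x$atoms),
              x$nterm, x$cterm))
  for (i in seq_along(x$residues)) {
    bb <- get_bb_angles(x, i)
    chi <- get_chi_angles(x, i)
    cat(sprintf("  %d %s  phi=%7.2f psi=%7.2f omega=%7.2f%s\n", i,
                .aa1to3[[x$residues[i]]], bb[1L], bb[2L], bb[3L],
                if (length(chi)) paste0("  chi=", paste(sprintf("%.2f", chi),
                                                        collapse = ", ")) else ""))
  }
  invisible(x)
}
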