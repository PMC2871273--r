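# Backbone representation and construction from internal coordinates.
#
# A chain is modelled with four backbone atoms per residue (N, CA, C, O) plus
# a pseudo-C-beta placed geometrically where a side-chain centroid would sit.
# Construction uses ideal covalent geometry (Engh--Huber-style bond lengths
# and angles), so a chain is fully determined by its sequence and its
# (phi, psi, omega) torsion angles.

# ideal bond lengths (Angstrom) and bond angles (degrees)
.bond <- c(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.530)
.angle <- c(n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7, ca_c_o = 120.8)

# the fully extended conformation used when a chain is grown
.extended <- c(phi = -150, psi = 150, omega = 180)

.aa1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

.cross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.unit <- function(v) v / sqrt(sum(v * v))

#' Wrap an angle into (-180, 180]
#'
#' @param a numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

# dihedral angle p1-p2-p3-p4 in degrees, in (-180, 180]
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  wrap_angle(atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi)
}

# natural-extension reference frame placement: position d with |c-d| = bond,
# angle(b, c, d) = angle and dihedral(a, b, c, d) = dihedral (degrees)
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  d2 <- c(-bond * cos(ang), bond * cos(tor) * sin(ang), -bond * sin(tor) * sin(ang))
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- cbind(bc, .cross(n, bc), n)
  c + as.numeric(m %*% d2)
}

#' Construct a backbone structure object
#'
#' @param sequence one-letter amino-acid string or character vector.
#' @param xyz numeric array of dimension `n x 4 x 3`; second dimension holds
#'   the N, CA, C, O atoms in that order.
#' @param chain_id single chain identifier character.
#' @param meta free-form provenance list (algorithm, stage, seed, original
#'   residue numbering, ...).
#' @return an object of class `fold_structure`. Residues are implicitly
#'   numbered 1..n, contiguously.
#' @export
fold_structure <- function(sequence, xyz, chain_id = "A", meta = list()) {
  seq <- split_sequence(sequence)
  n <- length(seq)
  if (n < 1L) stop("sequence length must be >= 1", call. = FALSE)
  if (!is.array(xyz) || !identical(dim(xyz), c(n, 4L, 3L)))
    stop("xyz must be an n x 4 x 3 array matching the sequence", call. = FALSE)
  if (!all(is.finite(xyz))) stop("all backbone coordinates must be finite", call. = FALSE)
  dimnames(xyz) <- list(NULL, c("N", "CA", "C", "O"), NULL)
  structure(list(sequence = seq, xyz = xyz,
                 chain_id = as.character(chain_id)[1L], meta = meta),
            class = "fold_structure")
}

#' @export
print.fold_structure <- function(x, ...) {
  cat(sprintf("<fold_structure> %d residues, chain %s\n", n_residues(x), x$chain_id))
  cat("  sequence: ", sequence_string(x), "\n", sep = "")
  if (length(x$meta)) cat("  meta: ", paste(names(x$meta), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of residues in a structure
#' @param s a `fold_structure`.
#' @export
n_residues <- function(s) length(s$sequence)

#' Sequence of a structure as a single string
#' @param s a `fold_structure`.
#' @export
sequence_string <- function(s) paste(s$sequence, collapse = "")

#' C-alpha coordinate matrix (n x 3)
#' @param s a `fold_structure`.
#' @export
ca_coords <- function(s) {
  m <- s$xyz[, "CA", , drop = FALSE]
  dim(m) <- c(dim(s$xyz)[1L], 3L)
  m
}

split_sequence <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) != 1L)
    sequence <- strsplit(sequence, "")[[1]]
  as.character(sequence)
}

# pseudo-C-beta from the N, CA, C positions (tetrahedral construction);
# glycine gets none
.pseudo_cb <- function(n, ca, c) {
  v1 <- .unit(n - ca)
  v2 <- .unit(c - ca)
  bis <- .unit(v1 + v2)
  perp <- .unit(.cross(v2, v1))
  alpha <- 54.75 * pi / 180
  ca + .bond[["ca_cb"]] * (-cos(alpha) * bis + sin(alpha) * perp)
}

#' Flat atom table for a structure
#'
#' Returns every backbone atom (and, optionally, the pseudo-C-beta of each
#' non-glycine residue) as a coordinate matrix with residue index, atom name
#' and element annotations. Used by the clash and energy machinery.
#'
#' @param s a `fold_structure`.
#' @param cb include pseudo-C-beta atoms for non-glycine residues?
#' @return list with `xyz` (m x 3), `res` (residue index), `name`, `element`.
#' @export
atom_table <- function(s, cb = TRUE) {
  n <- n_residues(s)
  names4 <- c("N", "CA", "C", "O")
  res <- rep(seq_len(n), each = 4L)
  name <- rep(names4, n)
  xyz <- matrix(aperm(s$xyz, c(2L, 1L, 3L)), ncol = 3L)
  if (cb) {
    has_cb <- which(s$sequence != "G")
    if (length(has_cb)) {
      cbx <- t(vapply(has_cb, function(i)
        .pseudo_cb(s$xyz[i, "N", ], s$xyz[i, "CA", ], s$xyz[i, "C", ]),
        numeric(3)))
      xyz <- rbind(xyz, cbx)
      res <- c(res, has_cb)
      name <- c(name, rep("CB", length(has_cb)))
      o <- order(res, match(name, c("N", "CA", "C", "O", "CB")))
      xyz <- xyz[o, , drop = FALSE]
      res <- res[o]
      name <- name[o]
    }
  }
  element <- substr(name, 1L, 1L)
  list(xyz = xyz, res = res, name = name, element = element)
}

# normalise a torsion input into an n x 3 matrix with columns phi, psi, omega
as_torsion_matrix <- function(torsions, n = NULL) {
  if (is.data.frame(torsions)) torsions <- as.matrix(torsions[c("phi", "psi", "omega")])
  if (is.numeric(torsions) && is.null(dim(torsions))) torsions <- matrix(torsions, ncol = 3L, byrow = TRUE)
  if (!is.matrix(torsions) || ncol(torsions) != 3L)
    stop("torsions must be an n x 3 matrix (phi, psi, omega)", call. = FALSE)
  colnames(torsions) <- c("phi", "psi", "omega")
  if (!is.null(n) && nrow(torsions) != n)
    stop("number of torsion triples (", nrow(torsions), ") does not match sequence length (", n, ")",
         call. = FALSE)
  torsions
}

#' Build a backbone from torsion angles
#'
#' Constructs an all-backbone chain with ideal covalent geometry from one
#' (phi, psi, omega) triple per residue. The first residue's phi and the last
#' residue's omega are not used; the last residue's psi only orients its
#' carbonyl oxygen. Angles are degrees in (-180, 180].
#'
#' @param sequence one-letter amino-acid string.
#' @param torsions n x 3 matrix (or data frame with columns `phi`, `psi`,
#'   `omega`), one row per residue.
#' @param chain_id chain identifier for the result.
#' @param meta provenance list.
#' @return a `fold_structure`; [extract_torsions()] on the result recovers the
#'   interior input angles to well within 0.5 degrees.
#' @examples
#' s <- build_from_torsions("AAAA", matrix(rep(c(-150, 150, 180), 4), ncol = 3, byrow = TRUE))
#' extract_torsions(s)
#' @export
build_from_torsions <- function(sequence, torsions, chain_id = "A", meta = list()) {
  seq <- split_sequence(sequence)
  n <- length(seq)
  if (n < 1L) stop("empty sequence", call. = FALSE)
  tm <- as_torsion_matrix(torsions, n)
  if (!all(is.finite(tm))) stop("all torsion angles must be finite", call. = FALSE)
  xyz <- array(NA_real_, dim = c(n, 4L, 3L),
               dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
  # first residue in a canonical frame
  ang <- .angle[["n_ca_c"]] * pi / 180
  xyz[1L, "N", ] <- c(0, 0, 0)
  xyz[1L, "CA", ] <- c(.bond[["n_ca"]], 0, 0)
  xyz[1L, "C", ] <- xyz[1L, "CA", ] + .bond[["ca_c"]] * c(-cos(ang), sin(ang), 0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      xyz[i + 1L, "N", ] <- .place_atom(xyz[i, "N", ], xyz[i, "CA", ], xyz[i, "C", ],
                                        .bond[["c_n"]], .angle[["ca_c_n"]], tm[i, "psi"])
      xyz[i + 1L, "CA", ] <- .place_atom(xyz[i, "CA", ], xyz[i, "C", ], xyz[i + 1L, "N", ],
                                         .bond[["n_ca"]], .angle[["c_n_ca"]], tm[i, "omega"])
      xyz[i + 1L, "C", ] <- .place_atom(xyz[i, "C", ], xyz[i + 1L, "N", ], xyz[i + 1L, "CA", ],
                                        .bond[["ca_c"]], .angle[["n_ca_c"]], tm[i + 1L, "phi"])
    }
  }
  # carbonyl oxygens: anti to the next amide nitrogen about the CA-C bond
  for (i in seq_len(n)) {
    psi <- if (is.na(tm[i, "psi"])) .extended[["psi"]] else tm[i, "psi"]
    xyz[i, "O", ] <- .place_atom(xyz[i, "N", ], xyz[i, "CA", ], xyz[i, "C", ],
                                 .bond[["c_o"]], .angle[["ca_c_o"]], psi - 180)
  }
  fold_structure(seq, xyz, chain_id = chain_id, meta = meta)
}

#' Extract torsion angles from a structure
#'
#' The inverse of [build_from_torsions()] up to numerical precision on chains
#' with ideal geometry, and the standard dihedral computation on any chain.
#' Undefined terminal angles (phi of the first residue, psi and omega of the
#' last) are reported as `NA`.
#'
#' @param s a `fold_structure` with at least two residues.
#' @return n x 3 matrix with columns `phi`, `psi`, `omega`, `NA` at the
#'   undefined terminal entries.
#' @export
extract_torsions <- function(s) {
  n <- n_residues(s)
  if (n < 2L) stop("torsions are undefined for a single-residue chain", call. = FALSE)
  tm <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("phi", "psi", "omega")))
  x <- s$xyz
  for (i in seq_len(n)) {
    if (i > 1L)
      tm[i, "phi"] <- .dihedral(x[i - 1L, "C", ], x[i, "N", ], x[i, "CA", ], x[i, "C", ])
    if (i < n) {
      tm[i, "psi"] <- .dihedral(x[i, "N", ], x[i, "CA", ], x[i, "C", ], x[i + 1L, "N", ])
      tm[i, "omega"] <- .dihedral(x[i, "CA", ], x[i, "C", ], x[i + 1L, "N", ], x[i + 1L, "CA", ])
    }
  }
  tm
}

# torsion matrix with the undefined terminal entries filled with the values
# used at build time (extended defaults), so a chain can be rebuilt exactly
.concrete_torsions <- function(s, default = .extended) {
  tm <- extract_torsions(s)
  if (is.na(tm[1L, "phi"])) tm[1L, "phi"] <- default[["phi"]]
  n <- nrow(tm)
  if (is.na(tm[n, "psi"])) tm[n, "psi"] <- default[["psi"]]
  if (is.na(tm[n, "omega"])) tm[n, "omega"] <- default[["omega"]]
  tm
}

#' Extend a chain at either terminus
#'
#' Appends `n_new` residues in a chosen conformation (fully extended by
#' default) at the C- or N-terminus. Placement continues the existing chain
#' geometrically, so the internal coordinates of pre-existing residues are
#' untouched; for `terminus = "N"` the old residues are implicitly renumbered
#' to keep indices contiguous from 1.
#'
#' @param s a `fold_structure`.
#' @param n_new number of residues to add (>= 1).
#' @param terminus `"C"` (append, the sense of translation) or `"N"` (prepend).
#' @param aa amino acids for the new residues (single string or vector,
#'   recycled; default alanine).
#' @param conformation length-3 vector `(phi, psi, omega)` for the new block;
#'   also used for the newly created junction angles.
#' @return the extended `fold_structure`.
#' @export
extend_chain <- function(s, n_new, terminus = c("C", "N"), aa = "A",
                         conformation = .extended) {
  terminus <- match.arg(terminus)
  if (!is.numeric(n_new) || n_new < 1L) stop("n_new must be >= 1", call. = FALSE)
  n_new <- as.integer(n_new)
  aa <- rep_len(split_sequence(aa), n_new)
  phi <- conformation[[1L]]; psi <- conformation[[2L]]; ome <- conformation[[3L]]
  n <- n_residues(s)
  x <- s$xyz
  new <- array(NA_real_, dim = c(n_new, 4L, 3L),
               dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
  if (terminus == "C") {
    pn <- x[n, "N", ]; pca <- x[n, "CA", ]; pc <- x[n, "C", ]
    for (j in seq_len(n_new)) {
      nn <- .place_atom(pn, pca, pc, .bond[["c_n"]], .angle[["ca_c_n"]], psi)
      nca <- .place_atom(pca, pc, nn, .bond[["n_ca"]], .angle[["c_n_ca"]], ome)
      nc <- .place_atom(pc, nn, nca, .bond[["ca_c"]], .angle[["n_ca_c"]], phi)
      new[j, "N", ] <- nn; new[j, "CA", ] <- nca; new[j, "C", ] <- nc
      pn <- nn; pca <- nca; pc <- nc
    }
    # re-place the old terminal oxygen: its psi is now defined by the junction
    x[n, "O", ] <- .place_atom(x[n, "N", ], x[n, "CA", ], x[n, "C", ],
                               .bond[["c_o"]], .angle[["ca_c_o"]], psi - 180)
    for (j in seq_len(n_new))
      new[j, "O", ] <- .place_atom(new[j, "N", ], new[j, "CA", ], new[j, "C", ],
                                   .bond[["c_o"]], .angle[["ca_c_o"]], psi - 180)
    xyz <- array(NA_real_, dim = c(n + n_new, 4L, 3L))
    xyz[seq_len(n), , ] <- x
    xyz[n + seq_len(n_new), , ] <- new
    seq_out <- c(s$sequence, aa)
  } else {
    # prepend: walk backwards placing C, CA, N of each new residue
    fc <- x[1L, "C", ]; fca <- x[1L, "CA", ]; fn <- x[1L, "N", ]
    for (j in seq_len(n_new)) {
      k <- n_new - j + 1L  # fill rows from the junction outwards
      nc <- .place_atom(fc, fca, fn, .bond[["c_n"]], .angle[["c_n_ca"]], phi)
      nca <- .place_atom(fca, fn, nc, .bond[["ca_c"]], .angle[["ca_c_n"]], ome)
      nn <- .place_atom(fn, nc, nca, .bond[["n_ca"]], .angle[["n_ca_c"]], psi)
      new[k, "N", ] <- nn; new[k, "CA", ] <- nca; new[k, "C", ] <- nc
      fc <- nc; fca <- nca; fn <- nn
    }
    for (j in seq_len(n_new))
      new[j, "O", ] <- .place_atom(new[j, "N", ], new[j, "CA", ], new[j, "C", ],
                                   .bond[["c_o"]], .angle[["ca_c_o"]], psi - 180)
    xyz <- array(NA_real_, dim = c(n + n_new, 4L, 3L))
    xyz[seq_len(n_new), , ] <- new
    xyz[n_new + seq_len(n), , ] <- x
    seq_out <- c(aa, s$sequence)
  }
  fold_structure(seq_out, xyz, chain_id = s$chain_id, meta = s$meta)
}
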