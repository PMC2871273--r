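# Three-state secondary structure assignment (H/E/C) from coordinates, via a
# Kabsch--Sander-style backbone hydrogen-bond analysis, plus ingestion of
# externally computed DSSP-style label strings.

# pairwise Euclidean distances between the rows of A and B
.cdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# Kabsch-Sander electrostatic hydrogen-bond energy, kcal/mol.
# E[i, j]: carbonyl C=O of residue i accepting from amide N-H of residue j.
# Amide hydrogens are placed 1 A from N along the previous residue's C->O
# direction reversed (the classic DSSP construction); residue 1 and prolines
# have no donor. Entries with |i - j| <= 1 are NA.
.hbond_energy <- function(s) {
  n <- n_residues(s)
  Nx <- s$xyz[, "N", , drop = FALSE]; dim(Nx) <- c(n, 3L)
  Ox <- s$xyz[, "O", , drop = FALSE]; dim(Ox) <- c(n, 3L)
  Cx <- s$xyz[, "C", , drop = FALSE]; dim(Cx) <- c(n, 3L)
  Hx <- matrix(NA_real_, n, 3L)
  for (j in 2:n) {
    d <- Cx[j - 1L, ] - Ox[j - 1L, ]
    Hx[j, ] <- Nx[j, ] + d / sqrt(sum(d * d))
  }
  q <- 27.888  # 0.084 e^2 * 332 in kcal/mol*A
  rON <- .cdist(Ox, Nx); rCH <- .cdist(Cx, Hx)
  rOH <- .cdist(Ox, Hx); rCN <- .cdist(Cx, Nx)
  E <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  E[is.na(E)] <- Inf
  E <- pmax(E, -9.9)
  no_donor <- c(TRUE, s$sequence[-1L] == "P")
  E[, no_donor] <- Inf
  near <- abs(outer(seq_len(n), seq_len(n), "-")) <= 1L
  E[near] <- Inf
  E
}

new_ss_assignment <- function(labels, source = c("computed", "external")) {
  source <- match.arg(source)
  structure(list(labels = labels, source = source), class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat(sprintf("<ss_assignment> (%s) %s\n", x$source, x$labels))
  invisible(x)
}

#' Assign three-state secondary structure from coordinates
#'
#' A simplified Kabsch--Sander assigner: backbone hydrogen bonds are detected
#' with the electrostatic criterion (energy below -0.5 kcal/mol, amide
#' hydrogens placed geometrically), n-turns (n = 3, 4, 5) with two consecutive
#' starts mark helical residues (the 8-state G/H/I classes, collapsed to H),
#' parallel and antiparallel bridge patterns mark strand residues (B/E
#' collapsed to E, single-residue gaps inside a ladder closed), and everything
#' else is coil.
#'
#' @param s a `fold_structure` (at least 5 residues; shorter chains come back
#'   all-coil with a warning).
#' @return an `ss_assignment` with one H/E/C character per residue.
#' @export
assign_ss <- function(s) {
  n <- n_residues(s)
  if (n < 5L) {
    warning("chain shorter than 5 residues: returning all-coil")
    return(new_ss_assignment(strrep("C", n), "computed"))
  }
  E <- .hbond_energy(s)
  hb <- E < -0.5
  lab <- rep("C", n)
  # bridges -> strand
  is_e <- rep(FALSE, n)
  for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      if (abs(i - j) < 3L) next
      para <- (hb[i - 1L, j] && hb[j, i + 1L]) || (hb[j - 1L, i] && hb[i, j + 1L])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (para || anti) is_e[c(i, j)] <- TRUE
    }
  }
  # close single-residue gaps inside ladders
  for (i in 2:(n - 1L)) if (!is_e[i] && is_e[i - 1L] && is_e[i + 1L]) is_e[i] <- TRUE
  lab[is_e] <- "E"
  # n-turns with two consecutive starts -> helix (takes precedence)
  is_h <- rep(FALSE, n)
  for (k in c(4L, 3L, 5L)) {
    turn <- rep(FALSE, n)
    for (i in seq_len(n - k)) turn[i] <- hb[i, i + k]
    if (n - k >= 2L) {
      for (i in 2:(n - k)) {
        if (turn[i - 1L] && turn[i]) is_h[i:(i + k - 1L)] <- TRUE
      }
    }
  }
  lab[is_h] <- "H"
  new_ss_assignment(paste(lab, collapse = ""), "computed")
}

.collapse_8to3 <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
                    T = "C", S = "C", C = "C", "-" = "C", "." = "C", " " = "C")

#' Read secondary-structure labels from a file
#'
#' Accepts either a bare label string (possibly wrapped over several lines) or
#' a whitespace-delimited two-column table (residue index, label). Eight-state
#' DSSP classes are collapsed to three states (G/H/I to H, B/E to E, the rest
#' to C); any character outside the known alphabet is an error.
#'
#' @param path text file.
#' @return an `ss_assignment` with `source = "external"`.
#' @export
read_ss_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  tokens <- strsplit(trimws(lines), "\\s+")
  chars <- if (all(lengths(tokens) >= 2L) && length(tokens) > 1L)
    vapply(tokens, function(t) t[[2L]], character(1))
  else
    strsplit(paste(vapply(tokens, function(t) paste(t, collapse = ""), character(1)),
                   collapse = ""), "")[[1]]
  parse_ss_string(paste(chars, collapse = ""))
}

#' Parse and validate a secondary-structure label string
#'
#' @param labels character string over the 8-state DSSP alphabet (collapsed to
#'   H/E/C) or already three-state.
#' @return an `ss_assignment` with `source = "external"`.
#' @export
parse_ss_string <- function(labels) {
  chars <- strsplit(toupper(labels), "")[[1]]
  mapped <- .collapse_8to3[chars]
  bad <- which(is.na(mapped))
  if (length(bad))
    stop("unknown secondary-structure characters at position(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(chars[bad]), collapse = ""), call. = FALSE)
  new_ss_assignment(paste(mapped, collapse = ""), "external")
}

new_ss_element <- function(kind, start, end) {
  structure(list(kind = kind, start = start, end = end), class = "ss_element")
}

#' Locate secondary-structure elements
#'
#' An element is a maximal run of at least four residues with identical helix
#' or strand assignment; coil runs are never elements.
#'
#' @param a an `ss_assignment` (or a bare label string).
#' @return list of elements, each with `kind` (H or E), `start`, `end`
#'   (1-based, inclusive), in chain order.
#' @export
find_elements <- function(a) {
  labels <- if (inherits(a, "ss_assignment")) a$labels else a
  chars <- strsplit(labels, "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("H", "E") & r$lengths >= 4L
  mapply(function(k, s, e) new_ss_element(k, s, e),
         r$values[keep], starts[keep], ends[keep],
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
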