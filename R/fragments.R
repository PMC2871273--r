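# Torsion-fragment libraries for insertion moves.
#
# Rosetta-style fragment databases need sequence profiles and a curated PDB;
# here candidate fragments are drawn from idealized secondary-structure motifs
# (with optional Gaussian torsion noise and a per-residue propensity bias), or
# harvested as contiguous torsion windows from user-supplied structures.

# motif (phi, psi) centres
.motifs <- list(
  helix    = c(phi = -57,  psi = -47),
  strand   = c(phi = -120, psi = 130),
  ppii     = c(phi = -75,  psi = 145),
  extended = c(phi = -150, psi = 150)
)

# simple per-residue motif propensities (relative weights); rows sum to taste,
# only ratios matter
.propensity <- local({
  p <- matrix(1, nrow = 20, ncol = 4,
              dimnames = list(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                              c("helix", "strand", "ppii", "extended")))
  p[c("A", "E", "L", "M", "Q", "K", "R", "H"), "helix"] <- 2.5
  p[c("V", "I", "Y", "F", "W", "T", "C"), "strand"] <- 2.5
  p[c("V", "I", "Y", "F", "W", "T", "C"), "extended"] <- 1.5
  p[c("G", "N", "D", "S"), "ppii"] <- 1.8
  p["P", "ppii"] <- 3
  p["P", "helix"] <- 0.3
  p
})

# run code under a temporary RNG state seeded with `seed`
local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

new_fragment <- function(triples, source_label = "") {
  triples <- as_torsion_matrix(triples)
  structure(list(length = nrow(triples), triples = triples,
                 source_label = source_label),
            class = "torsion_fragment")
}

new_fragment_library <- function(by_position, fragment_length, n_res) {
  structure(list(by_position = by_position, fragment_length = fragment_length,
                 n_res = n_res),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("<fragment_library> %d-mers at %d positions, %s candidates each\n",
              x$fragment_length, length(x$by_position),
              paste(range(lengths(x$by_position)), collapse = "-")))
  invisible(x)
}

#' Number of insertion positions covered by a library
#' @param lib a `fragment_library`.
#' @export
n_positions <- function(lib) length(lib$by_position)

check_fragment_length <- function(fragment_length) {
  if (!fragment_length %in% c(3L, 9L))
    stop("fragment_length must be 3 or 9", call. = FALSE)
  as.integer(fragment_length)
}

#' Generate an idealized motif fragment library
#'
#' For every insertion window of the target sequence, draws candidate
#' fragments from the four canonical backbone motifs (alpha-helix, beta-strand,
#' polyproline II and extended), weighting motifs by a per-residue propensity
#' table averaged over the window, and adding Gaussian noise of the requested
#' standard deviation to phi and psi. Omega stays near 180 degrees (noise one
#' tenth of `noise_deg`). Deterministic given `seed`.
#'
#' @param sequence target amino-acid sequence (one-letter string).
#' @param fragment_length 3 or 9.
#' @param per_position number of candidate fragments per window.
#' @param noise_deg torsion noise standard deviation, degrees (>= 0).
#' @param seed integer seed.
#' @return a `fragment_library` covering positions 1 .. (n - length + 1).
#' @export
make_idealized_library <- function(sequence, fragment_length = 9L, per_position = 20L,
                                   noise_deg = 15, seed = 1L) {
  fragment_length <- check_fragment_length(fragment_length)
  seq <- split_sequence(sequence)
  n <- length(seq)
  if (per_position < 1L) stop("per_position must be >= 1", call. = FALSE)
  if (noise_deg < 0) stop("noise_deg must be >= 0", call. = FALSE)
  if (n < fragment_length)
    stop("sequence shorter than fragment_length", call. = FALSE)
  n_pos <- n - fragment_length + 1L
  motif_mat <- do.call(rbind, .motifs)
  local_seed(seed, {
    by_position <- lapply(seq_len(n_pos), function(p) {
      window <- seq[p:(p + fragment_length - 1L)]
      known <- window[window %in% rownames(.propensity)]
      w <- if (length(known)) colMeans(.propensity[known, , drop = FALSE]) else rep(1, 4)
      lapply(seq_len(per_position), function(r) {
        m <- sample.int(4L, 1L, prob = w)
        phi <- wrap_angle(motif_mat[m, "phi"] + stats::rnorm(fragment_length, 0, noise_deg))
        psi <- wrap_angle(motif_mat[m, "psi"] + stats::rnorm(fragment_length, 0, noise_deg))
        ome <- wrap_angle(180 + stats::rnorm(fragment_length, 0, noise_deg / 10))
        new_fragment(cbind(phi = phi, psi = psi, omega = ome),
                     source_label = sprintf("motif:%s", rownames(motif_mat)[m]))
      })
    })
    new_fragment_library(by_position, fragment_length, n)
  })
}

#' Harvest a fragment library from structures
#'
#' Extracts every fully-defined contiguous torsion window from the supplied
#' structures and, for each target window, ranks candidates by a BLOSUM62
#' similarity score between the candidate's source sequence window and the
#' target window (ties broken by source order). The target's own experimental
#' structure should not be among `pdb_paths` for an honest ab initio setup.
#'
#' @param pdb_paths character vector of PDB file paths, or a list of
#'   `fold_structure` objects.
#' @param sequence target sequence.
#' @param fragment_length 3 or 9.
#' @param per_position candidates kept per window; if fewer windows exist,
#'   all are returned with a warning.
#' @return a `fragment_library`.
#' @export
harvest_library <- function(pdb_paths, sequence, fragment_length = 9L, per_position = 20L) {
  fragment_length <- check_fragment_length(fragment_length)
  seq <- split_sequence(sequence)
  n <- length(seq)
  structures <- lapply(pdb_paths, function(p)
    if (inherits(p, "fold_structure")) p else read_pdb(p))
  labels <- if (is.character(pdb_paths)) basename(pdb_paths) else
    sprintf("structure%02d", seq_along(structures))
  windows <- list(); win_seq <- list(); win_lab <- character()
  for (si in seq_along(structures)) {
    s <- structures[[si]]
    tm <- extract_torsions(s)
    ns <- n_residues(s)
    # fully defined windows only: phi needs start >= 2, psi/omega end <= ns - 1
    starts <- if (ns - fragment_length >= 2L) 2L:(ns - fragment_length) else integer()
    for (p in starts) {
      idx <- p:(p + fragment_length - 1L)
      windows[[length(windows) + 1L]] <- tm[idx, , drop = FALSE]
      win_seq[[length(win_seq) + 1L]] <- s$sequence[idx]
      win_lab <- c(win_lab, sprintf("%s:%d", labels[[si]], p))
    }
  }
  if (!length(windows)) stop("no valid torsion windows found in the input structures", call. = FALSE)
  if (length(windows) < per_position)
    warning(sprintf("only %d windows available; returning all of them per position",
                    length(windows)))
  blosum <- .blosum62()
  n_pos <- n - fragment_length + 1L
  by_position <- lapply(seq_len(n_pos), function(p) {
    target <- seq[p:(p + fragment_length - 1L)]
    score <- vapply(win_seq, function(ws) {
      ok <- ws %in% rownames(blosum) & target %in% colnames(blosum)
      sum(blosum[cbind(ws[ok], target[ok])])
    }, numeric(1))
    keep <- order(-score, seq_along(score))[seq_len(min(per_position, length(windows)))]
    lapply(keep, function(k) new_fragment(windows[[k]], source_label = win_lab[k]))
  })
  new_fragment_library(by_position, fragment_length, n)
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Serialize a fragment library to TSV
#'
#' Long format: one row per (position, rank, residue) with the torsion triple
#' and the candidate's source label.
#'
#' @param lib a `fragment_library`.
#' @param path output file.
#' @export
write_fragment_library <- function(lib, path) {
  rows <- list()
  for (p in seq_along(lib$by_position)) {
    for (r in seq_along(lib$by_position[[p]])) {
      fr <- lib$by_position[[p]][[r]]
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, rank = r, residue = seq_len(fr$length),
        phi = fr$triples[, "phi"], psi = fr$triples[, "psi"],
        omega = fr$triples[, "omega"], source_label = fr$source_label)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fragment library written by [write_fragment_library()]
#'
#' @param path TSV file.
#' @param n_res chain length the library applies to (defaults to the largest
#'   position plus fragment length minus one).
#' @export
read_fragment_library <- function(path, n_res = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  k <- max(df$residue)
  by_position <- lapply(sort(unique(df$position)), function(p) {
    dp <- df[df$position == p, ]
    lapply(sort(unique(dp$rank)), function(r) {
      dr <- dp[dp$rank == r, ][order(dp$residue[dp$rank == r]), ]
      new_fragment(cbind(phi = dr$phi, psi = dr$psi, omega = dr$omega),
                   source_label = dr$source_label[1L])
    })
  })
  new_fragment_library(by_position, as.integer(k),
                       n_res %||% (length(by_position) + k - 1L))
}
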