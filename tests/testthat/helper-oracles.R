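# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities through different code paths
# (subset enumeration, igraph bond distances, bio3d fitting, scalar loops)
# than the package implementations they check.

ref_tor <- function(n, v) {
  matrix(rep(v, n), ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, c("phi", "psi", "omega")))
}

ideal_helix <- function(n, aa = "A") {
  build_from_torsions(strrep(aa, n), ref_tor(n, c(-57, -47, 180)))
}

ideal_extended <- function(n, aa = "A") {
  build_from_torsions(strrep(aa, n), ref_tor(n, c(-150, 150, 180)))
}

random_rigid_motion <- function(xyz) {
  # QR of a random matrix gives a uniform-ish rotation; force det +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(xyz %*% t(q), 2, stats::rnorm(3, sd = 10), "+")
}

apply_rigid_motion_structure <- function(s, seed = 1) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    tr <- stats::rnorm(3, sd = 10)
    xyz <- s$xyz
    for (a in 1:4) xyz[, a, ] <- sweep(xyz[, a, , drop = FALSE][, 1, ] %*% t(q), 2, tr, "+")
    fold_structure(s$sequence, xyz, s$chain_id, s$meta)
  })
}

# Brute-force GDT counts by exhaustive subset enumeration: for every subset of
# >= 3 residues, superpose on the subset and count inliers at each cutoff.
brute_gdt_counts <- function(mod, nat, cutoffs = c(1, 2, 4, 8)) {
  n <- nrow(mod)
  stopifnot(n <= 12)
  best <- setNames(rep(0L, length(cutoffs)), paste0("N", cutoffs))
  for (k in 3:n) {
    combos <- utils::combn(n, k)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      fit <- kabsch_superpose(mod[idx, , drop = FALSE], nat[idx, , drop = FALSE])
      moved <- sweep(tcrossprod(mod, fit$rotation), 2, fit$translation, "+")
      dev <- sqrt(rowSums((moved - nat)^2))
      for (j in seq_along(cutoffs)) {
        cnt <- sum(dev <= cutoffs[j])
        if (cnt > best[j]) best[j] <- cnt
      }
    }
  }
  best
}

# Independent clash count: bond separations from igraph shortest paths over
# the covalent graph; pairs more than 3 bonds apart with overlap > 0.4.
brute_clash_count <- function(s) {
  at <- atom_table(s, cb = TRUE)
  m <- length(at$res)
  edges <- integer()
  idx <- function(r, nm) which(at$res == r & at$name == nm)
  for (r in seq_len(max(at$res))) {
    e <- rbind(c(idx(r, "N"), idx(r, "CA")), c(idx(r, "CA"), idx(r, "C")),
               c(idx(r, "C"), idx(r, "O")))
    cb <- idx(r, "CB")
    if (length(cb)) e <- rbind(e, c(idx(r, "CA"), cb))
    if (r < max(at$res)) e <- rbind(e, c(idx(r, "C"), idx(r + 1L, "N")))
    edges <- c(edges, t(e))
  }
  g <- igraph::make_graph(edges, n = m, directed = FALSE)
  sep <- igraph::distances(g)
  radii <- c(C = 1.70, N = 1.55, O = 1.52)[at$element]
  cnt <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (sep[i, j] <= 3) next
      d <- sqrt(sum((at$xyz[i, ] - at$xyz[j, ])^2))
      if (radii[i] + radii[j] - d > 0.4) cnt <- cnt + 1L
    }
  }
  cnt
}

# Scalar-loop run-length element finder
brute_elements <- function(labels) {
  chars <- strsplit(labels, "")[[1]]
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    j <- i
    while (j < length(chars) && chars[j + 1L] == chars[i]) j <- j + 1L
    if (chars[i] %in% c("H", "E") && j - i + 1L >= 4L)
      out[[length(out) + 1L]] <- list(kind = chars[i], start = i, end = j)
    i <- j + 1L
  }
  out
}

# Exact two-sided binomial sign-test p by direct summation (binom.test's
# likelihood-based two-sided definition)
brute_sign_p <- function(wins, losses) {
  n <- wins + losses
  if (n == 0) return(1)
  probs <- stats::dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[wins + 1L] * (1 + 1e-7)])
}

# Per-window mean distance using bio3d's independent least-squares fitting
brute_window_profile <- function(mod, nat, window = 11L) {
  n <- nrow(mod)
  half <- (window - 1L) %/% 2L
  vals <- rep(NA_real_, n)
  for (start in seq_len(n - window + 1L)) {
    idx <- start:(start + window - 1L)
    a <- as.numeric(t(mod[idx, , drop = FALSE]))
    b <- as.numeric(t(nat[idx, , drop = FALSE]))
    moved <- bio3d::fit.xyz(fixed = b, mobile = a,
                            fixed.inds = seq_along(b), mobile.inds = seq_along(a))
    dm <- matrix(moved, ncol = 3L, byrow = TRUE) - nat[idx, , drop = FALSE]
    vals[start + half] <- mean(sqrt(rowSums(dm^2)))
  }
  vals
}

# Scalar Kabsch-Sander hydrogen-bond counter (acceptor i, donor j)
brute_hbonds <- function(s, cutoff = -0.5) {
  n <- n_residues(s)
  x <- s$xyz
  cnt <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || j == 1 || s$sequence[j] == "P") next
      hdir <- x[j - 1, "C", ] - x[j - 1, "O", ]
      h <- x[j, "N", ] + hdir / sqrt(sum(hdir^2))
      dist <- function(a, b) sqrt(sum((a - b)^2))
      e <- 27.888 * (1 / dist(x[i, "O", ], x[j, "N", ]) + 1 / dist(x[i, "C", ], h) -
                     1 / dist(x[i, "O", ], h) - 1 / dist(x[i, "C", ], x[j, "N", ]))
      if (e < cutoff) cnt <- cnt + 1L
    }
  }
  cnt
}

# --- mirror-image helpers for the forward/reverse equivalence oracle ---

mirror_torsions <- function(tm, keep_last_omega = 180) {
  n <- nrow(tm)
  cbind(phi = rev(tm[, "psi"]), psi = rev(tm[, "phi"]),
        omega = c(rev(tm[-n, "omega"]), keep_last_omega))
}

mirror_library <- function(lib) {
  n <- lib$n_res
  k <- lib$fragment_length
  lib$by_position <- lapply(seq_len(n_positions(lib)), function(qp) {
    q <- n - qp - k + 2L
    lapply(lib$by_position[[q]], function(fr) {
      fr$triples <- cbind(phi = rev(fr$triples[, "psi"]),
                          psi = rev(fr$triples[, "phi"]),
                          omega = c(rev(fr$triples[-k, "omega"]), 180))
      fr
    })
  })
  lib
}

# torsion-only energy, symmetric under the phi/psi mirror swap
mirror_symmetric_energy <- function(seqv, tm) {
  rad <- pi / 180
  sum(cos(tm[, "phi"] * rad) + cos(tm[, "psi"] * rad) +
      0.3 * sin(2 * tm[, "phi"] * rad) + 0.3 * sin(2 * tm[, "psi"] * rad)) +
    sum(cos(tm[, "omega"] * rad))
}

reverse_string <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")

# a library whose only candidate everywhere is the extended motif (no-op
# insertions on an extended chain)
extended_only_library <- function(sequence, k = 9L) {
  n <- nchar(sequence)
  frag <- cotransfold:::new_fragment(ref_tor(k, c(-150, 150, 180)), "extended")
  cotransfold:::new_fragment_library(
    replicate(n - k + 1L, list(frag), simplify = FALSE), k, n)
}
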