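# Coarse backbone energy for Monte Carlo folding: soft-sphere repulsion,
# radius-of-gyration compactness, backbone hydrogen-bond reward and a torsion
# propensity penalty. Deliberately simple -- its job is to make compact,
# hydrogen-bonded, clash-free chains score better than extended or tangled
# ones, reproducibly and fast.

.vdw_radius <- c(C = 1.70, N = 1.55, O = 1.52)

# cache of nonbonded pair masks keyed by sequence + cb flag
.nb_cache <- new.env(parent = emptyenv())

# Atom pairs excluded from nonbonded terms: covalent bond separation <= 3
# (1-2, 1-3 and 1-4 pairs, the standard exclusion; 1-4 backbone pairs such as
# O(i)..CA(i+1) sit inside summed van-der-Waals radii in every trans peptide
# and would otherwise register as permanent clashes).
.nonbonded_excluded <- function(at) {
  m <- length(at$res)
  adj <- vector("list", m)
  add_bond <- function(i, j) {
    adj[[i]] <<- c(adj[[i]], j)
    adj[[j]] <<- c(adj[[j]], i)
  }
  idx <- function(r, name) which(at$res == r & at$name == name)
  n_res <- max(at$res)
  for (r in seq_len(n_res)) {
    iN <- idx(r, "N"); iCA <- idx(r, "CA"); iC <- idx(r, "C"); iO <- idx(r, "O")
    add_bond(iN, iCA); add_bond(iCA, iC); add_bond(iC, iO)
    iCB <- idx(r, "CB")
    if (length(iCB)) add_bond(iCA, iCB)
    if (r < n_res) add_bond(iC, idx(r + 1L, "N"))
  }
  excl <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    # breadth-first to depth 3
    frontier <- i
    seen <- i
    for (d in 1:3) {
      frontier <- unique(unlist(adj[frontier]))
      frontier <- setdiff(frontier, seen)
      if (!length(frontier)) break
      seen <- c(seen, frontier)
      excl[i, frontier] <- TRUE
    }
  }
  excl | t(excl)
}

.nonbonded_mask <- function(s, cb = TRUE) {
  key <- paste0(sequence_string(s), if (cb) "+cb" else "")
  hit <- .nb_cache[[key]]
  if (!is.null(hit)) return(hit)
  at <- atom_table(s, cb = cb)
  out <- list(at_res = at$res, at_name = at$name, element = at$element,
              excluded = .nonbonded_excluded(at))
  .nb_cache[[key]] <- out
  out
}

#' Energy weights
#'
#' @param w_clash soft-sphere repulsion weight.
#' @param w_rg radius-of-gyration compactness weight.
#' @param w_hbond backbone hydrogen-bond reward weight.
#' @param w_rama torsion-propensity penalty weight.
#' @return an `energy_weights` list; all weights must be non-negative and at
#'   least one positive.
#' @export
energy_weights <- function(w_clash = 1, w_rg = 1, w_hbond = 0.5, w_rama = 0.25) {
  w <- list(w_clash = w_clash, w_rg = w_rg, w_hbond = w_hbond, w_rama = w_rama)
  if (any(unlist(w) < 0)) stop("energy weights must be >= 0", call. = FALSE)
  if (all(unlist(w) == 0)) stop("at least one energy weight must be > 0", call. = FALSE)
  class(w) <- "energy_weights"
  w
}

#' Coarse backbone energy of a conformation
#'
#' The total is `w_clash * clash + w_rg * rg - w_hbond * hbonds +
#' w_rama * rama` where `clash` sums squared van-der-Waals overlaps over
#' nonbonded backbone and pseudo-C-beta atom pairs, `rg` is the C-alpha radius
#' of gyration relative to the globular expectation `2.2 n^0.38`, `hbonds`
#' counts Kabsch--Sander backbone hydrogen bonds, and `rama` penalises
#' (phi, psi) pairs far from the canonical motif basins.
#'
#' @param s a `fold_structure`.
#' @param w an [energy_weights()] list.
#' @param torsions optional precomputed torsion matrix (avoids re-extraction).
#' @return numeric energy (finite); the individual terms are attached as the
#'   `"components"` attribute.
#' @export
chain_energy <- function(s, w = energy_weights(), torsions = NULL) {
  n <- n_residues(s)
  nb <- .nonbonded_mask(s, cb = TRUE)
  at <- atom_table(s, cb = TRUE)
  d <- as.matrix(stats::dist(at$xyz))
  r <- .vdw_radius[at$element]
  r0 <- outer(r, r, "+")
  overlap <- r0 - d
  overlap[nb$excluded] <- 0
  overlap[lower.tri(overlap, diag = TRUE)] <- 0
  clash <- sum(pmax(overlap, 0)^2)
  ca <- ca_coords(s)
  cen <- colMeans(ca)
  rg <- sqrt(mean(rowSums((ca - rep(cen, each = n))^2))) / (2.2 * n^0.38)
  hbonds <- if (n >= 5L) sum(.hbond_energy(s) < -0.5) else 0L
  tm <- if (is.null(torsions)) .concrete_torsions(s) else torsions
  motif_mat <- do.call(rbind, .motifs)
  dev2 <- vapply(seq_len(n), function(i) {
    min((wrap_angle(tm[i, "phi"] - motif_mat[, "phi"]))^2 +
        (wrap_angle(tm[i, "psi"] - motif_mat[, "psi"]))^2)
  }, numeric(1))
  rama <- mean(pmin(dev2, 120^2)) / 120^2
  comp <- c(clash = clash, rg = rg, hbonds = hbonds, rama = rama)
  total <- w$w_clash * clash + w$w_rg * rg - w$w_hbond * hbonds + w$w_rama * rama
  structure(total, components = comp)
}
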