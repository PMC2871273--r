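# Model-versus-native evaluation: optimal superposition, GDT_TS, local
# 11-residue window quality, directional sense differences, terminus
# trimming, steric clashscore and the previous-contact (ALR) statistic.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `R %*% A + t` onto `B`.
#'
#' @param A,B n x 3 coordinate matrices (n >= 3, matched rows).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3) and
#'   `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3L)
    stop("A and B must be matched n x 3 matrices", call. = FALSE)
  if (nrow(A) < 3L) stop("at least 3 points are required", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  s <- svd(crossprod(A0, B0))
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cb - as.numeric(R %*% ca)
  fitted <- sweep(tcrossprod(A, R), 2L, tr, "+")
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((fitted - B)^2))))
}

.apply_superposition <- function(A, fit) sweep(tcrossprod(A, fit$rotation), 2L, fit$translation, "+")

# residues placeable within `cutoff` under the best superposition found by a
# deterministic seed-and-refine search: seed fits from every contiguous
# segment of lengths 4, 8, 16 and the whole chain, each walked down a cutoff
# ladder (4c, 2c, c) and then iterated (fit on inliers, recompute inliers)
# to a fixpoint, at most 10 rounds per rung
.gdt_count_heuristic <- function(mod, nat, cutoff) {
  n <- nrow(mod)
  seg_lengths <- unique(pmin(c(4L, 8L, 16L, n), n))
  seg_lengths <- seg_lengths[seg_lengths >= 3L]
  best <- 0L
  deviations <- function(idx) {
    fit <- kabsch_superpose(mod[idx, , drop = FALSE], nat[idx, , drop = FALSE])
    sqrt(rowSums((.apply_superposition(mod, fit) - nat)^2))
  }
  for (len in seg_lengths) {
    for (start in seq_len(n - len + 1L)) {
      idx <- start:(start + len - 1L)
      for (rung in c(4, 2, 1) * cutoff) {
        for (iter in seq_len(10L)) {
          dev <- deviations(idx)
          inliers <- which(dev <= rung)
          # keep the fit alive when few residues make the cut
          if (length(inliers) < 3L) inliers <- order(dev)[1:3]
          cnt <- sum(dev <= cutoff)
          if (cnt > best) best <- cnt
          if (identical(inliers, idx)) break
          idx <- inliers
        }
      }
      cnt <- sum(deviations(idx) <= cutoff)
      if (cnt > best) best <- cnt
    }
  }
  best
}

# exact counts for tiny chains: enumerate every residue subset of size >= 3,
# superpose on it, and count inliers
.gdt_count_exact <- function(mod, nat, cutoffs) {
  n <- nrow(mod)
  best <- setNames(rep(0L, length(cutoffs)), paste0("N", cutoffs))
  for (k in 3:n) {
    combos <- utils::combn(n, k)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      fit <- kabsch_superpose(mod[idx, , drop = FALSE], nat[idx, , drop = FALSE])
      dev <- sqrt(rowSums((.apply_superposition(mod, fit) - nat)^2))
      for (j in seq_along(cutoffs)) {
        cnt <- sum(dev <= cutoffs[j])
        if (cnt > best[j]) best[j] <- cnt
      }
    }
  }
  best
}

#' Global Distance Test total score
#'
#' `GDT_TS = 100 (N1 + N2 + N4 + N8) / (4N)` where `N_c` is the number of
#' corresponding C-alpha atoms placeable within `c` Angstrom of the native
#' under an optimal rigid superposition; closer residues are weighted more
#' heavily. The superposition search is a deterministic seed-and-refine
#' heuristic (contiguous-segment seeds of lengths 4, 8, 16 and the whole
#' chain, iterative inlier refitting).
#'
#' @param model,native `fold_structure` objects of equal length with 1:1
#'   residue correspondence by index (or bare n x 3 C-alpha matrices).
#' @param method `"auto"` (exact subset enumeration up to 12 residues, the
#'   seed-and-refine heuristic beyond), `"heuristic"`, or `"exact"` (subset
#'   enumeration; only feasible for small chains).
#' @return a `gdt_result`: cumulative counts `N1 N2 N4 N8`, chain length `N`,
#'   `gdt_ts`, and non-cumulative shell counts `M1 M2 M4 M8`.
#' @export
gdt_ts <- function(model, native, method = c("auto", "heuristic", "exact")) {
  method <- match.arg(method)
  mod <- if (inherits(model, "fold_structure")) ca_coords(model) else as.matrix(model)
  nat <- if (inherits(native, "fold_structure")) ca_coords(native) else as.matrix(native)
  if (nrow(mod) != nrow(nat))
    stop("model and native must have the same number of residues", call. = FALSE)
  n <- nrow(mod)
  if (method == "auto") method <- if (n <= 12L) "exact" else "heuristic"
  if (method == "exact" && n > 16L)
    stop("exact subset enumeration is only feasible for small chains", call. = FALSE)
  counts <- if (method == "exact")
    as.numeric(.gdt_count_exact(mod, nat, c(1, 2, 4, 8)))
  else
    vapply(c(1, 2, 4, 8), function(cutoff) .gdt_count_heuristic(mod, nat, cutoff),
           numeric(1))
  counts <- as.integer(cummax(counts))  # a larger shell can never hold fewer
  names(counts) <- c("N1", "N2", "N4", "N8")
  m <- c(M1 = counts[["N1"]], M2 = counts[["N2"]] - counts[["N1"]],
         M4 = counts[["N4"]] - counts[["N2"]], M8 = counts[["N8"]] - counts[["N4"]])
  structure(list(N1 = counts[["N1"]], N2 = counts[["N2"]], N4 = counts[["N4"]],
                 N8 = counts[["N8"]], N = n,
                 gdt_ts = 100 * sum(counts) / (4 * n),
                 noncumulative = m),
            class = "gdt_result")
}

#' @export
print.gdt_result <- function(x, ...) {
  cat(sprintf("<gdt_result> N=%d  N1=%d N2=%d N4=%d N8=%d  GDT_TS=%.2f\n",
              x$N, x$N1, x$N2, x$N4, x$N8, x$gdt_ts))
  invisible(x)
}

#' Local prediction quality along the chain (11-residue windows)
#'
#' Every contiguous window of `window` residues of the decoy is independently
#' superposed (Kabsch, on its C-alphas) onto the corresponding native window;
#' the mean residual C-alpha--C-alpha distance is assigned to the window's
#' centre residue. Centre residues without a full window are `NA`.
#'
#' @param decoy,native equal-length `fold_structure` objects (or C-alpha
#'   matrices), at least `window` residues.
#' @param window odd window size, default 11.
#' @return a `window_profile`: data frame with `residue` and `mean_dist`.
#' @export
window_quality_profile <- function(decoy, native, window = 11L) {
  mod <- if (inherits(decoy, "fold_structure")) ca_coords(decoy) else as.matrix(decoy)
  nat <- if (inherits(native, "fold_structure")) ca_coords(native) else as.matrix(native)
  if (nrow(mod) != nrow(nat)) stop("decoy and native lengths differ", call. = FALSE)
  n <- nrow(mod)
  if (n < window) stop("chain shorter than the window", call. = FALSE)
  half <- (window - 1L) %/% 2L
  vals <- rep(NA_real_, n)
  for (start in seq_len(n - window + 1L)) {
    idx <- start:(start + window - 1L)
    fit <- kabsch_superpose(mod[idx, , drop = FALSE], nat[idx, , drop = FALSE])
    moved <- .apply_superposition(mod[idx, , drop = FALSE], fit)
    vals[start + half] <- mean(sqrt(rowSums((moved - nat[idx, , drop = FALSE])^2)))
  }
  structure(data.frame(residue = seq_len(n), mean_dist = vals),
            class = c("window_profile", "data.frame"), window = window)
}

# mean window-profile value over residues carrying a given native label
.class_quality <- function(decoys, native, labels, class, window) {
  per_decoy <- vapply(decoys, function(d) {
    s <- if (inherits(d, "folding_result")) d$final else d
    prof <- window_quality_profile(s, native, window)
    sel <- which(labels == class & !is.na(prof$mean_dist))
    if (!length(sel)) return(NA_real_)
    mean(prof$mean_dist[sel])
  }, numeric(1))
  mean(per_decoy)
}

#' Directional difference in local prediction quality
#'
#' For each decoy the window-quality profile is averaged over residues that
#' are helical (respectively strand) in the native assignment; these are
#' averaged over each decoy set, and the forward mean is subtracted from the
#' reverse mean per class. Positive values mean the forward (N-to-C) decoys
#' are locally more accurate. A class absent from the native yields `NA`
#' (such proteins are excluded from strand analyses).
#'
#' @param forward_decoys,reverse_decoys non-empty lists of `fold_structure`
#'   or `folding_result` objects.
#' @param native the experimental structure.
#' @param native_ss `ss_assignment` for the native.
#' @param window window size for [window_quality_profile()].
#' @return named numeric `c(helix_diff, strand_diff)` in Angstrom.
#' @export
sense_difference <- function(forward_decoys, reverse_decoys, native, native_ss,
                             window = 11L) {
  if (!length(forward_decoys) || !length(reverse_decoys))
    stop("both decoy sets must be non-empty", call. = FALSE)
  labels <- strsplit(native_ss$labels, "")[[1]]
  if (length(labels) != n_residues(native))
    stop("native_ss length does not match the native structure", call. = FALSE)
  out <- vapply(c(helix_diff = "H", strand_diff = "E"), function(cl) {
    if (!any(labels == cl)) return(NA_real_)
    fwd <- .class_quality(forward_decoys, native, labels, cl, window)
    rev <- .class_quality(reverse_decoys, native, labels, cl, window)
    rev - fwd
  }, numeric(1))
  out
}

#' Trim unstructured termini guided by the native secondary structure
#'
#' Removes model residues before the first and after the last native
#' secondary-structure element (run of >= 4 identical H or E labels). The
#' first and last elements must span at least five residues counted from the
#' end of the first to the start of the last, inclusive; otherwise (or when
#' fewer than one element exists) the model is returned untrimmed with
#' attribute `trimmed = FALSE`.
#'
#' @param model a `fold_structure`.
#' @param native_ss `ss_assignment` of the corresponding native.
#' @return the trimmed (renumbered) or original structure; attributes
#'   `trimmed` (logical) and `kept` (retained residue range of the input).
#' @export
trim_termini <- function(model, native_ss) {
  labels <- if (inherits(native_ss, "ss_assignment")) native_ss$labels else native_ss
  if (nchar(labels) != n_residues(model))
    stop("label string does not match model length", call. = FALSE)
  els <- find_elements(labels)
  skip <- function(msg) {
    message("trim_termini: ", msg, "; returning the model untrimmed")
    structure(model, trimmed = FALSE, kept = c(1L, n_residues(model)))
  }
  if (length(els) < 1L) return(skip("no secondary-structure elements"))
  first <- els[[1L]]; last <- els[[length(els)]]
  if (last$start - first$end + 1L < 5L)
    return(skip("terminal elements are separated by fewer than five residues"))
  keep <- first$start:last$end
  out <- fold_structure(model$sequence[keep], model$xyz[keep, , , drop = FALSE],
                        chain_id = model$chain_id, meta = model$meta)
  structure(out, trimmed = TRUE, kept = c(first$start, last$end))
}

#' Steric clashscore
#'
#' Counts van-der-Waals overlaps greater than 0.4 Angstrom between nonbonded
#' atom pairs (covalent separation of more than three bonds) over the
#' backbone plus pseudo-C-beta atom model, normalised per 1000 atoms. Radii:
#' C 1.70, N 1.55, O 1.52 Angstrom.
#'
#' @param s a `fold_structure`.
#' @return a `clash_report`: `n_atoms`, `n_overlaps`, `clashscore`.
#' @export
clashscore <- function(s) {
  at <- atom_table(s, cb = TRUE)
  m <- length(at$res)
  if (m < 2L) stop("need at least two atoms", call. = FALSE)
  nb <- .nonbonded_mask(s, cb = TRUE)
  d <- as.matrix(stats::dist(at$xyz))
  r <- .vdw_radius[at$element]
  overlap <- outer(r, r, "+") - d
  overlap[nb$excluded] <- -Inf
  overlap[lower.tri(overlap, diag = TRUE)] <- -Inf
  n_overlaps <- sum(overlap > 0.4)
  structure(list(n_atoms = m, n_overlaps = n_overlaps,
                 clashscore = 1000 * n_overlaps / m),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("<clash_report> %d atoms, %d overlaps > 0.4 A, clashscore %.2f\n",
              x$n_atoms, x$n_overlaps, x$clashscore))
  invisible(x)
}

#' Clashscore change on blind extension of a partial chain
#'
#' For each of the extruded lengths 18, 36, 54, 72 and 90, takes the folded
#' intermediate of that length, measures its clashscore, adds nine residues
#' in fully extended conformation at the growing terminus (C for forward
#' decoys, N for reverse), measures again, and records after minus before.
#' Returns the mean of the five differences.
#'
#' @param result a `folding_result` from a sequential run on a chain of at
#'   least 99 residues.
#' @param mode `"forward"` or `"reverse"`; defaults to the result's own mode.
#' @param lengths extruded lengths examined.
#' @return list with `deltas` (named numeric, one per length) and
#'   `mean_delta`.
#' @export
clash_extension_delta <- function(result, mode = NULL,
                                  lengths = c(18L, 36L, 54L, 72L, 90L)) {
  mode <- mode %||% result$mode
  if (!mode %in% c("forward", "reverse"))
    stop("mode must be forward or reverse", call. = FALSE)
  full_seq <- result$final$sequence
  n <- length(full_seq)
  inter_len <- vapply(result$intermediates, n_residues, integer(1))
  deltas <- vapply(lengths, function(l) {
    k <- which(inter_len == l)
    if (!length(k))
      stop("no intermediate of length ", l, " in the folding result", call. = FALSE)
    s <- result$intermediates[[k[1L]]]
    before <- clashscore(s)$clashscore
    aa <- if (mode == "forward") full_seq[(l + 1L):(l + 9L)] else
      full_seq[(n - l - 8L):(n - l)]
    ext <- extend_chain(s, 9L, terminus = if (mode == "forward") "C" else "N", aa = aa)
    clashscore(ext)$clashscore - before
  }, numeric(1))
  names(deltas) <- paste0("len", lengths)
  list(deltas = deltas, mean_delta = mean(deltas))
}

#' Average logarithmic ratio of previous contacts
#'
#' Measures whether residues contact predominantly earlier-synthesised
#' (N-terminal side) or later-synthesised partners. A contact is a C-alpha
#' pair within `cutoff` Angstrom at sequence separation >= `sep_min`. For
#' residue `i`, `p_i` counts contacts to residues `j <= i - sep_min` and
#' `s_i` contacts to `j >= i + sep_min`; the statistic is the mean of
#' `log2((p_i + 1/2) / (s_i + 1/2))` over residues with at least one
#' long-range contact. Positive values indicate a bias toward previous
#' contacts. By construction the statistic of the index-reversed chain is the
#' exact negation.
#'
#' @param s a `fold_structure` longer than `2 * sep_min`.
#' @param sep_min minimum sequence separation (default 5).
#' @param cutoff contact distance cutoff in Angstrom (default 8).
#' @return a `contact_stats`: per-residue `previous` and `subsequent` counts,
#'   `alr`, number of contributing residues `n_contributing`, and
#'   `no_contacts` flag (ALR reported as 0 when no residue has a long-range
#'   contact).
#' @export
alr <- function(s, sep_min = 5L, cutoff = 8) {
  n <- n_residues(s)
  if (n <= 2L * sep_min) stop("chain too short for the contact analysis", call. = FALSE)
  ca <- ca_coords(s)
  d <- as.matrix(stats::dist(ca))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  contact <- d <= cutoff & sep >= sep_min
  lower <- outer(seq_len(n), seq_len(n), ">")  # j < i
  p <- unname(rowSums(contact & lower))
  ss <- unname(rowSums(contact & !lower))
  use <- p + ss > 0
  val <- if (any(use)) mean(log2((p[use] + 0.5) / (ss[use] + 0.5))) else 0
  structure(list(previous = p, subsequent = ss, alr = val,
                 n_contributing = sum(use), no_contacts = !any(use)),
            class = "contact_stats")
}

#' @export
print.contact_stats <- function(x, ...) {
  cat(sprintf("<contact_stats> ALR = %.4f over %d residues with long-range contacts\n",
              x$alr, x$n_contributing))
  invisible(x)
}
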