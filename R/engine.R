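# Monte Carlo fragment-assembly folding in three modes: sequential from the
# N-terminus (the sense of translation), reverse sequential from the
# C-terminus, and non-sequential from a fully extended chain. All three share
# one Metropolis annealer and one total cycle budget; a cycle is one attempted
# fragment insertion.

#' Allocate Monte Carlo cycles for a chain
#'
#' The total number of cycles scales linearly with chain length from a base
#' number per 100 residues: `t = round(b * l / 100)`. Sequential folding
#' spreads these evenly across the `e = ceiling(l / 9)` nine-residue
#' extrusions: `n = floor(t / e)` cycles for the first `e - 1` extrusions and
#' `t - n (e - 1)` for the final one. The final extrusion may be shorter than
#' nine residues.
#'
#' @param b base cycles per 100 residues (>= 1).
#' @param l chain length in residues (>= 1).
#' @return a `folding_schedule` with fields `b`, `l`, `t`, `e`, `n`, `last`
#'   and `extrusion_sizes`.
#' @examples
#' allocate_cycles(34000, 100)  # t = 34000, e = 12
#' allocate_cycles(34000, 143)  # t = 48620: 1.43 times the base
#' @export
allocate_cycles <- function(b, l) {
  if (!is.numeric(b) || !is.numeric(l) || b < 1 || l < 1)
    stop("b and l must be positive", call. = FALSE)
  l <- as.integer(l)
  t <- as.integer(floor(b * l / 100 + 0.5))
  e <- as.integer(ceiling(l / 9))
  n <- t %/% e
  last <- t - n * (e - 1L)
  sizes <- c(rep(9L, e - 1L), l - 9L * (e - 1L))
  structure(list(b = b, l = l, t = t, e = e, n = n, last = last,
                 extrusion_sizes = sizes),
            class = "folding_schedule")
}

#' @export
print.folding_schedule <- function(x, ...) {
  cat(sprintf("<folding_schedule> l=%d b=%s: t=%d cycles over e=%d extrusions (%d + final %d)\n",
              x$l, format(x$b), x$t, x$e, x$n, x$last))
  invisible(x)
}

# geometric temperature ladder over one stage
.temperature_ladder <- function(cycles, t_hi = 2, t_lo = 0.25) {
  if (cycles <= 1L) return(rep(t_hi, max(cycles, 0L)))
  t_hi * (t_lo / t_hi)^((seq_len(cycles) - 1) / (cycles - 1))
}

# Metropolis fragment-insertion search on a torsion matrix.
# Insertion windows are enumerated from the oldest extruded residue outwards
# (ascending starts for forward-sense chains, descending for reverse-sense),
# and exactly three uniform draws are consumed per trial (window, candidate,
# acceptance), so runs with a shared seed are comparable across senses.
# A fragment overwrites phi and psi of its whole window but only its k - 1
# internal peptide omegas; the junction omega to the following residue is
# kept.
.anneal_torsions <- function(seqv, tm, lib, cycles, active_range, w, temps,
                             sense = "forward", lib_offset = 0L, energy_fn = NULL) {
  k <- lib$fragment_length
  eval_energy <- function(t_mat) {
    if (!is.null(energy_fn)) return(as.numeric(energy_fn(seqv, t_mat)))
    as.numeric(chain_energy(build_from_torsions(seqv, t_mat), w, torsions = t_mat))
  }
  cur_e <- eval_energy(tm)
  if (cycles == 0L)
    return(list(torsions = tm, energy = cur_e, trials = 0L, accepted = 0L))
  hi <- active_range[2L] - k + 1L
  starts <- if (hi < active_range[1L]) integer() else seq.int(active_range[1L], hi)
  starts <- starts[starts >= 1L & starts + lib_offset >= 1L &
                   starts + lib_offset <= n_positions(lib)]
  if (!length(starts))
    stop("no eligible insertion windows inside the active range", call. = FALSE)
  if (sense == "reverse") starts <- rev(starts)
  if (is.null(temps)) temps <- .temperature_ladder(cycles)
  best_t <- cur_t <- tm
  best_e <- cur_e
  accepted <- 0L
  for (i in seq_len(cycles)) {
    u1 <- stats::runif(1L); u2 <- stats::runif(1L); u3 <- stats::runif(1L)
    p <- starts[max(1L, ceiling(u1 * length(starts)))]
    cands <- lib$by_position[[p + lib_offset]]
    fr <- cands[[max(1L, ceiling(u2 * length(cands)))]]
    idx <- p:(p + k - 1L)
    new_t <- cur_t
    new_t[idx, "phi"] <- fr$triples[, "phi"]
    new_t[idx, "psi"] <- fr$triples[, "psi"]
    new_t[idx[-k], "omega"] <- fr$triples[-k, "omega"]
    new_e <- eval_energy(new_t)
    de <- new_e - cur_e
    if (de <= 0 || u3 < exp(-de / temps[i])) {
      cur_t <- new_t
      cur_e <- new_e
      accepted <- accepted + 1L
      if (cur_e < best_e) {
        best_t <- cur_t
        best_e <- cur_e
      }
    }
  }
  list(torsions = best_t, energy = best_e, trials = cycles, accepted = accepted)
}

#' One Metropolis folding stage on a structure
#'
#' Runs `cycles` attempted fragment insertions restricted to windows fully
#' inside `active_range`, with Metropolis acceptance on a geometric
#' temperature ladder, and returns the lowest-energy conformation visited
#' (which is never worse than the input). Randomness comes from the current
#' RNG state; seed with [set.seed()] or use the `fold_*` drivers.
#'
#' @param s a `fold_structure` built by this package (ideal geometry).
#' @param lib a `fragment_library`.
#' @param cycles number of trials (>= 0; 0 returns the input unchanged).
#' @param active_range residue interval `c(lo, hi)` open to insertions
#'   (default: the whole chain).
#' @param w an [energy_weights()] list.
#' @param temps optional explicit temperature vector of length `cycles`.
#' @param sense `"forward"` or `"reverse"`: which terminus is the growing one
#'   (fixes the window enumeration order; the choice among windows is uniform
#'   either way).
#' @param lib_offset offset added to chain positions to index `lib` (used when
#'   `s` is a suffix of the library's target sequence).
#' @param energy_fn optional replacement energy, called as
#'   `energy_fn(sequence_chars, torsion_matrix)`; defaults to [chain_energy()].
#' @return the folded `fold_structure`, with attributes `energy` (best energy)
#'   and `trials` (Metropolis trials executed).
#' @export
fold_stage <- function(s, lib, cycles, active_range = NULL, w = energy_weights(),
                       temps = NULL, sense = c("forward", "reverse"),
                       lib_offset = 0L, energy_fn = NULL) {
  sense <- match.arg(sense)
  if (cycles < 0) stop("cycles must be >= 0", call. = FALSE)
  n <- n_residues(s)
  if (is.null(active_range)) active_range <- c(1L, n)
  if (active_range[1L] < 1L || active_range[2L] > n || active_range[1L] > active_range[2L])
    stop("active_range must lie within the chain", call. = FALSE)
  tm <- .concrete_torsions(s)
  res <- .anneal_torsions(s$sequence, tm, lib, as.integer(cycles), active_range,
                          w, temps, sense, as.integer(lib_offset), energy_fn)
  out <- build_from_torsions(s$sequence, res$torsions, chain_id = s$chain_id, meta = s$meta)
  attr(out, "energy") <- res$energy
  attr(out, "trials") <- res$trials
  attr(out, "torsions") <- res$torsions
  out
}

new_folding_result <- function(final, intermediates, energies, seed, mode,
                               schedule, trials) {
  structure(list(final = final, intermediates = intermediates,
                 trajectory_energies = energies, seed = seed, mode = mode,
                 schedule = schedule, trials = trials),
            class = "folding_result")
}

#' @export
print.folding_result <- function(x, ...) {
  cat(sprintf("<folding_result> mode=%s, %d residues, %d stage(s), %d trials, seed=%s\n",
              x$mode, n_residues(x$final), length(x$intermediates), x$trials,
              format(x$seed)))
  invisible(x)
}

#' Sequential (cotranslational) folding
#'
#' Emulates folding during synthesis: the chain grows by nine-residue
#' extrusions added in fully extended conformation at the C-terminus
#' (`sense = "forward"`, the sense of translation) or at the N-terminus
#' (`sense = "reverse"`), and after each extrusion the entire currently
#' extruded chain is annealed for its share of the cycle budget. The
#' conformation reached at each stage (lowest energy visited) seeds the next.
#'
#' @param sequence full-length amino-acid sequence.
#' @param lib fragment library built for `sequence`.
#' @param schedule a [allocate_cycles()] schedule with `l == nchar(sequence)`.
#' @param sense `"forward"` (N to C) or `"reverse"` (C to N).
#' @param w an [energy_weights()] list.
#' @param seed integer seed; the run is deterministic given it.
#' @param temps optional per-stage temperature vectors (list of length `e`).
#' @param energy_fn optional energy override, see [fold_stage()].
#' @param conformation torsion triple for newly extruded residues
#'   (fully extended by default).
#' @return a `folding_result`: final full-length structure, one intermediate
#'   per extrusion stage, per-stage best energies, and the trial counter
#'   (always equal to `schedule$t`).
#' @export
fold_sequential <- function(sequence, lib, schedule, sense = c("forward", "reverse"),
                            w = energy_weights(), seed = 1L, temps = NULL,
                            energy_fn = NULL, conformation = .extended) {
  sense <- match.arg(sense)
  seqv <- split_sequence(sequence)
  n <- length(seqv)
  if (n != schedule$l)
    stop("schedule length (", schedule$l, ") does not match sequence length (", n, ")",
         call. = FALSE)
  sizes <- schedule$extrusion_sizes
  cyc <- c(rep(schedule$n, schedule$e - 1L), schedule$last)
  phi <- conformation[[1L]]; psi <- conformation[[2L]]; ome <- conformation[[3L]]
  local_seed(seed, {
    tm <- NULL
    cur_len <- 0L
    intermediates <- vector("list", schedule$e)
    energies <- numeric(schedule$e)
    trials <- 0L
    for (k in seq_len(schedule$e)) {
      size <- sizes[k]
      block <- matrix(rep(c(phi, psi, ome), size), ncol = 3L, byrow = TRUE,
                      dimnames = list(NULL, c("phi", "psi", "omega")))
      if (is.null(tm)) {
        tm <- block
      } else if (sense == "forward") {
        tm[cur_len, c("psi", "omega")] <- c(psi, ome)  # junction, newly defined
        tm <- rbind(tm, block)
      } else {
        tm <- rbind(block, tm)
        tm[size + 1L, "phi"] <- phi  # junction, newly defined
      }
      cur_len <- cur_len + size
      chunk <- if (sense == "forward") seqv[seq_len(cur_len)] else
        seqv[(n - cur_len + 1L):n]
      offset <- if (sense == "forward") 0L else n - cur_len
      st <- .anneal_torsions(chunk, tm, lib, cyc[k], c(1L, cur_len), w,
                             if (is.list(temps)) temps[[k]] else temps,
                             sense, offset, energy_fn)
      tm <- st$torsions
      trials <- trials + st$trials
      energies[k] <- st$energy
      intermediates[[k]] <- build_from_torsions(
        chunk, tm,
        meta = list(algorithm = if (sense == "forward") "sequential" else "reverse_sequential",
                    stage = k, seed = seed))
    }
    final <- intermediates[[schedule$e]]
    new_folding_result(final, intermediates, energies, seed,
                       if (sense == "forward") "forward" else "reverse",
                       schedule, trials)
  })
}

#' Non-sequential folding from a fully extended chain
#'
#' The whole chain is built in extended conformation and annealed in a single
#' stage with the full cycle budget; this is the non-sequential baseline the
#' sequential modes are compared against.
#'
#' @inheritParams fold_sequential
#' @param total_cycles Metropolis trials (use `allocate_cycles(b, l)$t` for a
#'   budget-matched comparison).
#' @return a `folding_result` with no intermediates.
#' @export
fold_nonsequential <- function(sequence, lib, total_cycles, w = energy_weights(),
                               seed = 1L, temps = NULL, energy_fn = NULL,
                               conformation = .extended) {
  seqv <- split_sequence(sequence)
  n <- length(seqv)
  tm <- matrix(rep(unlist(conformation), n), ncol = 3L, byrow = TRUE,
               dimnames = list(NULL, c("phi", "psi", "omega")))
  local_seed(seed, {
    st <- .anneal_torsions(seqv, tm, lib, as.integer(total_cycles), c(1L, n), w,
                           temps, "forward", 0L, energy_fn)
    final <- build_from_torsions(seqv, st$torsions,
                                 meta = list(algorithm = "nonsequential", seed = seed))
    new_folding_result(final, list(), st$energy, seed, "nonsequential",
                       NULL, st$trials)
  })
}

#' Generate a decoy set
#'
#' Runs `n_decoys` independent folding simulations; decoy `i` uses seed
#' `base_seed + i`, so sets are reproducible in any execution order.
#'
#' @param mode `"forward"`, `"reverse"` or `"nonsequential"`.
#' @param sequence target sequence.
#' @param lib fragment library for the sequence.
#' @param b base cycles per 100 residues (shared budget across modes).
#' @param n_decoys number of decoys (>= 1).
#' @param w an [energy_weights()] list.
#' @param base_seed integer; decoy seeds are `base_seed + 1 .. base_seed + n`.
#' @param ... passed on to the folding drivers.
#' @return list of `folding_result`.
#' @export
generate_decoys <- function(mode = c("forward", "reverse", "nonsequential"),
                            sequence, lib, b, n_decoys, w = energy_weights(),
                            base_seed = 0L, ...) {
  mode <- match.arg(mode)
  if (n_decoys < 1L) stop("n_decoys must be >= 1", call. = FALSE)
  seqv <- split_sequence(sequence)
  schedule <- allocate_cycles(b, length(seqv))
  lapply(seq_len(n_decoys), function(i) {
    seed <- as.integer(base_seed + i)
    if (mode == "nonsequential")
      fold_nonsequential(seqv, lib, schedule$t, w, seed = seed, ...)
    else
      fold_sequential(seqv, lib, schedule, sense = mode, w = w, seed = seed, ...)
  })
}
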