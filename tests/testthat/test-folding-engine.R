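test_that("cycle allocation reproduces the published arithmetic", {
  s <- allocate_cycles(34000, 100)
  expect_equal(s$t, 34000L)
  expect_equal(s$e, 12L)
  expect_equal(s$n, 2833L)
  expect_equal(s$last, 2837L)

  expect_equal(allocate_cycles(34000, 143)$t, 48620L)  # 1.43 x base

  s101 <- allocate_cycles(34000, 101)
  expect_equal(s101$e, 12L)
  expect_equal(s101$extrusion_sizes, c(rep(9L, 11), 2L))

  s1 <- allocate_cycles(12, 9)
  expect_equal(unlist(s1[c("t", "e", "n", "last")]), c(t = 1L, e = 1L, n = 1L, last = 1L))

  expect_error(allocate_cycles(0, 10), "positive")
})

test_that("schedule invariants hold over random (b, l)", {
  withr::with_seed(100, {
    for (i in 1:100) {
      b <- sample(1:50000, 1)
      l <- sample(9:400, 1)
      s <- allocate_cycles(b, l)
      expect_equal(s$t, as.integer(floor(b * l / 100 + 0.5)))
      expect_equal(s$e, as.integer(ceiling(l / 9)))
      expect_equal(s$n, s$t %/% s$e)
      expect_equal(s$n * (s$e - 1L) + s$last, s$t)
      expect_gte(s$last, s$n)
      expect_equal(sum(s$extrusion_sizes), l)
      expect_true(all(s$extrusion_sizes[-s$e] == 9L))
      expect_true(s$extrusion_sizes[s$e] >= 1L && s$extrusion_sizes[s$e] <= 9L)
    }
  })
})

test_that("energy terms honour their monotonicity contracts", {
  w <- energy_weights()
  # two CA atoms forced close: strictly higher clash term than further apart
  base <- ideal_extended(6)
  near <- base; near$xyz[6, "CA", ] <- near$xyz[1, "CA", ] + c(1, 0, 0)
  far <- base;  far$xyz[6, "CA", ] <- far$xyz[1, "CA", ] + c(4, 0, 0)
  expect_gt(attr(chain_energy(near, w), "components")[["clash"]],
            attr(chain_energy(far, w), "components")[["clash"]])

  # extended 30-mer has a higher compactness (rg) term than a compact fold
  ext <- ideal_extended(30)
  compact <- make_toy_native(30, "helix-bundle", seed = 1)$structure
  expect_gt(attr(chain_energy(ext, w), "components")[["rg"]],
            attr(chain_energy(compact, w), "components")[["rg"]])

  # helix hydrogen bonds: package count and independent scalar count agree
  h <- ideal_helix(12)
  expect_gte(attr(chain_energy(h, w), "components")[["hbonds"]], 2)
  expect_equal(unname(attr(chain_energy(h, w), "components")[["hbonds"]]),
               brute_hbonds(h))
  expect_equal(unname(attr(chain_energy(ideal_extended(12), w), "components")[["hbonds"]]), 0)
})

test_that("fold_stage: zero cycles is the identity, T -> 0 rejects uphill moves", {
  s <- ideal_extended(12)
  lib <- make_idealized_library(strrep("A", 12), 9, 5, 10, seed = 1)
  out0 <- fold_stage(s, lib, 0)
  expect_equal(out0$xyz, s$xyz, tolerance = 1e-12)
  expect_equal(attr(out0, "trials"), 0L)

  # single uphill candidate at near-zero temperature: never accepted
  clashy <- cotransfold:::new_fragment(ref_tor(9, c(-57, 100, 180)), "bad")
  bad_lib <- cotransfold:::new_fragment_library(
    replicate(4, list(clashy), simplify = FALSE), 9L, 12L)
  uphill <- function(seqv, tm) sum(abs(wrap_angle(tm[, "psi"] - 150)))
  withr::with_seed(3, {
    out <- fold_stage(s, bad_lib, 50, temps = rep(1e-9, 50), energy_fn = uphill)
    expect_equal(out$xyz, s$xyz, tolerance = 1e-12)
  })
})

test_that("folding runs are deterministic given their seed, in all modes", {
  toy <- make_toy_native(20, "helix", seed = 2)
  lib <- make_idealized_library(toy$sequence, 9, 6, 15, seed = 3)
  sch <- allocate_cycles(100, 20)
  for (mode in c("forward", "reverse")) {
    a <- fold_sequential(toy$sequence, lib, sch, mode, seed = 11)
    b <- fold_sequential(toy$sequence, lib, sch, mode, seed = 11)
    expect_equal(a$final$xyz, b$final$xyz, tolerance = 1e-12)
  }
  a <- fold_nonsequential(toy$sequence, lib, sch$t, seed = 11)
  b <- fold_nonsequential(toy$sequence, lib, sch$t, seed = 11)
  expect_equal(a$final$xyz, b$final$xyz, tolerance = 1e-12)
})

test_that("sequential stages grow by the scheduled extrusion sizes", {
  seq101 <- strrep("A", 101)
  lib <- make_idealized_library(seq101, 9, 4, 10, seed = 5)
  sch <- allocate_cycles(12, 101)  # 12 trials over 12 stages
  fwd <- fold_sequential(seq101, lib, sch, "forward", seed = 1)
  expect_equal(vapply(fwd$intermediates, n_residues, integer(1)),
               c(seq(9L, 99L, by = 9L), 101L))
  expect_equal(fwd$trials, sch$t)

  rev <- fold_sequential(seq101, lib, sch, "reverse", seed = 1)
  # reverse intermediates hold the last sum(sizes) residues of the sequence
  expect_equal(vapply(rev$intermediates, n_residues, integer(1)),
               c(seq(9L, 99L, by = 9L), 101L))
  toyseq <- paste0(strrep("A", 92), "CDEFGHIKL")
  lib2 <- make_idealized_library(toyseq, 9, 4, 10, seed = 5)
  rev2 <- fold_sequential(toyseq, lib2, allocate_cycles(12, 101), "reverse", seed = 1)
  expect_identical(sequence_string(rev2$intermediates[[1]]), "CDEFGHIKL")
})

test_that("non-sequential folding starts from the fully extended state", {
  lib <- make_idealized_library(strrep("A", 15), 9, 4, 10, seed = 1)
  r <- fold_nonsequential(strrep("A", 15), lib, 0, seed = 1)
  tm <- extract_torsions(r$final)
  expect_lt(max(abs(wrap_angle(tm[2:14, ] - ref_tor(13, c(-150, 150, 180))))), 1e-9)
  expect_equal(r$trials, 0L)
  expect_length(r$intermediates, 0L)
})

test_that("decoy generation uses distinct, reproducible per-decoy seeds", {
  toy <- make_toy_native(18, "helix", seed = 6)
  lib <- make_idealized_library(toy$sequence, 9, 5, 15, seed = 7)
  d <- generate_decoys("forward", toy$sequence, lib, 50, 3, base_seed = 40)
  expect_equal(vapply(d, function(x) x$seed, integer(1)), 41:43)
  d2 <- generate_decoys("forward", toy$sequence, lib, 50, 3, base_seed = 40)
  for (i in 1:3) expect_equal(d[[i]]$final$xyz, d2[[i]]$final$xyz, tolerance = 1e-12)
  # equal seeds give identical structures even across call sites
  single <- fold_sequential(toy$sequence, lib, allocate_cycles(50, 18), "forward", seed = 42)
  expect_equal(single$final$xyz, d[[2]]$final$xyz, tolerance = 1e-12)
})

test_that("the returned conformation never scores worse than the stage start", {
  toy <- make_toy_native(24, "hairpin", seed = 8)
  lib <- make_idealized_library(toy$sequence, 9, 8, 20, seed = 9)
  w <- energy_weights()
  start <- ideal_extended(24, "V")
  e0 <- as.numeric(chain_energy(start, w))
  withr::with_seed(10, {
    out <- fold_stage(start, lib, 40, w = w)
    expect_lte(attr(out, "energy"), e0)
    expect_equal(as.numeric(chain_energy(out, w, torsions = attr(out, "torsions"))),
                 attr(out, "energy"), tolerance = 1e-9)
  })
})

test_that("reverse folding is the exact mirror of forward folding on the reversed problem", {
  withr::with_seed(99, {
    seq18 <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 18, TRUE),
                   collapse = "")
  })
  lib <- make_idealized_library(seq18, 9, 5, 20, seed = 4)
  sch <- allocate_cycles(120, 18)
  rev_run <- fold_sequential(seq18, lib, sch, "reverse", seed = 31,
                             energy_fn = mirror_symmetric_energy)
  fwd_run <- fold_sequential(reverse_string(seq18), mirror_library(lib), sch,
                             "forward", seed = 31,
                             energy_fn = mirror_symmetric_energy,
                             conformation = c(150, -150, 180))
  expect_equal(rev_run$trajectory_energies, fwd_run$trajectory_energies,
               tolerance = 1e-12)
  for (k in seq_along(rev_run$intermediates)) {
    tm_r <- extract_torsions(rev_run$intermediates[[k]])
    tm_f <- extract_torsions(fwd_run$intermediates[[k]])
    n <- nrow(tm_f)
    mirrored <- cbind(phi = rev(tm_f[, "psi"]), psi = rev(tm_f[, "phi"]),
                      omega = c(rev(tm_f[-n, "omega"]), NA))
    dev <- abs(wrap_angle(tm_r - mirrored))
    expect_lt(max(dev, na.rm = TRUE), 1e-9)
  }
})
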