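test_that("Kabsch superposition recovers exact rigid motions", {
  withr::with_seed(1, {
    A <- matrix(rnorm(30, sd = 5), 10, 3)
    B <- random_rigid_motion(A)
  })
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  same <- kabsch_superpose(A, A)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)
  expect_equal(same$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "3 points")
})

test_that("Kabsch rmsd equals a brute-force numeric minimisation", {
  A <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(3, 3, 0))
  B <- A; B[4, 3] <- 1  # one point displaced 1 A out of plane
  fit <- kabsch_superpose(A, B)
  euler <- function(p) {
    Rz <- matrix(c(cos(p[1]), -sin(p[1]), 0, sin(p[1]), cos(p[1]), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(p[2]), 0, sin(p[2]), 0, 1, 0, -sin(p[2]), 0, cos(p[2])), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(p[3]), -sin(p[3]), 0, sin(p[3]), cos(p[3])), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) {
    fitted <- sweep(A %*% t(euler(p)), 2, p[4:6], "+")
    sqrt(mean(rowSums((fitted - B)^2)))
  }
  o <- stats::optim(rep(0, 6), obj, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(fit$rmsd, o$value, tolerance = 1e-5)
})

test_that("GDT_TS is 100 for identical and rigidly moved models", {
  toy <- make_toy_native(20, "helix-bundle", seed = 1)
  g <- gdt_ts(toy$structure, toy$structure)
  expect_equal(g$gdt_ts, 100)
  expect_equal(c(g$N1, g$N2, g$N4, g$N8), rep(20L, 4))
  moved <- apply_rigid_motion_structure(toy$structure, seed = 2)
  expect_equal(gdt_ts(moved, toy$structure)$gdt_ts, 100)
  shifted <- toy$structure
  shifted$xyz <- shifted$xyz + 3  # uniform 3 A translation
  expect_equal(gdt_ts(shifted, toy$structure)$gdt_ts, 100)
  expect_error(gdt_ts(ca_coords(toy$structure)[1:10, ], toy$structure), "same number")
})

test_that("GDT counts match exhaustive subset enumeration on small chains", {
  # one residue of ten displaced 5 A: an optimal fit splits the error,
  # bringing all ten inside 4 A but only nine inside 2 A; here the
  # seed-and-refine heuristic finds the exhaustive-search optimum too
  withr::with_seed(5, nat <- matrix(rnorm(30, sd = 4), 10, 3))
  mod <- nat; mod[10, ] <- mod[10, ] + c(5, 0, 0)
  g <- gdt_ts(mod, nat)
  brute <- brute_gdt_counts(mod, nat)
  expect_equal(c(g$N1, g$N2, g$N4, g$N8), unname(brute))
  expect_equal(g$gdt_ts, 100 * sum(brute) / 40)
  gh <- gdt_ts(mod, nat, method = "heuristic")
  expect_equal(c(gh$N1, gh$N2, gh$N4, gh$N8), unname(brute))

  # random noisy toys stay within the exact path (n <= 12), and the
  # heuristic never beats the exact answer nor falls below a naive
  # whole-chain superposition
  withr::with_seed(6, {
    for (i in 1:3) {
      nat <- ca_coords(make_toy_native(9 + i, "helix", seed = i)$structure)
      mod <- nat + matrix(rnorm(length(nat), sd = runif(1, 0.5, 2)), nrow(nat))
      g <- gdt_ts(mod, nat)
      brute <- brute_gdt_counts(mod, nat)
      expect_equal(c(g$N1, g$N2, g$N4, g$N8), unname(cummax(brute)))
      gh <- gdt_ts(mod, nat, method = "heuristic")
      fit <- kabsch_superpose(mod, nat)
      dev <- sqrt(rowSums((sweep(tcrossprod(mod, fit$rotation), 2,
                                 fit$translation, "+") - nat)^2))
      for (cutoff in c(1, 2, 4, 8)) {
        expect_lte(gh[[paste0("N", cutoff)]], g[[paste0("N", cutoff)]])
        expect_gte(gh[[paste0("N", cutoff)]], sum(dev <= cutoff))
      }
    }
  })
})

test_that("GDT counts are cumulative and consistent with the shell weights", {
  toy <- make_toy_native(24, "mixed", seed = 3)
  dec <- make_decoy_set(toy$structure, 4, 3, seed = 4)
  for (d in dec) {
    g <- gdt_ts(d, toy$structure)
    expect_true(g$N1 <= g$N2 && g$N2 <= g$N4 && g$N4 <= g$N8 && g$N8 <= g$N)
    m <- g$noncumulative
    expect_equal(4 * m[["M1"]] + 3 * m[["M2"]] + 2 * m[["M4"]] + m[["M8"]],
                 g$N1 + g$N2 + g$N4 + g$N8)
    expect_true(g$gdt_ts >= 0 && g$gdt_ts <= 100)
  }
})

test_that("window profiles match an independent per-window computation", {
  toy <- make_toy_native(24, "hairpin", seed = 5)
  prof <- window_quality_profile(toy$structure, toy$structure)
  expect_true(all(prof$mean_dist[6:19] < 1e-9))
  expect_true(all(is.na(prof$mean_dist[c(1:5, 20:24)])))

  dec <- make_decoy_set(toy$structure, 1, 2, seed = 6)[[1]]
  prof2 <- window_quality_profile(dec, toy$structure)
  brute <- brute_window_profile(ca_coords(dec), ca_coords(toy$structure))
  expect_equal(prof2$mean_dist, brute, tolerance = 1e-6)

  # chain of exactly one window: single defined centre
  s11 <- ideal_helix(11)
  p11 <- window_quality_profile(s11, s11)
  expect_equal(which(!is.na(p11$mean_dist)), 6L)
  expect_error(window_quality_profile(ideal_helix(10), ideal_helix(10)), "shorter")
})

test_that("sense difference is zero for identical decoy sets and signed as documented", {
  toy <- make_toy_native(26, "mixed", seed = 7)
  ss <- assign_ss(toy$structure)
  dec <- make_decoy_set(toy$structure, 3, 1.5, seed = 8)
  expect_equal(unname(sense_difference(dec, dec, toy$structure, ss)),
               c(0, 0))
  # forward decoys exactly native, reverse perturbed: both differences positive
  exact <- make_decoy_set(toy$structure, 3, 0, seed = 9)
  d <- sense_difference(exact, dec, toy$structure, ss)
  expect_true(all(d > 0))
  # a native with no strand residues yields the NA sentinel for strands
  hel <- make_toy_native(30, "helix", seed = 10)
  dhel <- make_decoy_set(hel$structure, 2, 1, seed = 11)
  dd <- sense_difference(dhel, dhel, hel$structure, assign_ss(hel$structure))
  expect_true(is.na(dd[["strand_diff"]]))
  expect_equal(dd[["helix_diff"]], 0)
})

test_that("terminus trimming follows the element and separation rules", {
  s15 <- ideal_helix(15)
  t1 <- trim_termini(s15, parse_ss_string("CCHHHHCCCEEEECC"))
  expect_true(attr(t1, "trimmed"))
  expect_equal(attr(t1, "kept"), c(3L, 13L))
  expect_equal(n_residues(t1), 11L)

  expect_message(t2 <- trim_termini(s15, parse_ss_string(strrep("C", 15))), "untrimmed")
  expect_false(attr(t2, "trimmed"))
  expect_equal(n_residues(t2), 15L)

  s9 <- ideal_helix(9)
  expect_message(t3 <- trim_termini(s9, parse_ss_string("HHHHCEEEE")), "untrimmed")
  expect_false(attr(t3, "trimmed"))

  # trimming never removes residues between the terminal elements
  withr::with_seed(30, {
    for (i in 1:10) {
      lab <- paste(sample(c("H", "E", "C"), 20, TRUE, prob = c(.4, .3, .3)), collapse = "")
      s20 <- ideal_helix(20)
      tr <- suppressMessages(trim_termini(s20, parse_ss_string(lab)))
      els <- find_elements(lab)
      if (attr(tr, "trimmed")) {
        expect_equal(attr(tr, "kept"),
                     c(els[[1]]$start, els[[length(els)]]$end))
      }
    }
  })
})

test_that("clashscore counts overlaps beyond three covalent bonds, per 1000 atoms", {
  expect_equal(clashscore(ideal_extended(25, "G"))$clashscore, 0)
  hp <- make_toy_native(24, "hairpin", seed = 1)
  expect_equal(clashscore(hp$structure)$n_overlaps, 0L)

  # hand-built 100-atom toy: 25 glycines in an extended (near-planar) chain,
  # residue 20 lifted out of plane so its CA stacks 2.9 A above CA of residue
  # 5. The carbon pair overlaps by 3.4 - 2.9 = 0.5 > 0.4; every other pair
  # stays clear, so exactly one overlap in 100 atoms: clashscore 10.
  far <- build_from_torsions(strrep("G", 25), ref_tor(25, c(-150, 150, 180)))
  clash <- far
  shift <- clash$xyz[20, "CA", ] - clash$xyz[5, "CA", ] - c(0, 0, 2.9)
  clash$xyz[20, , ] <- sweep(clash$xyz[20, , ], 2, shift)
  at <- atom_table(clash, cb = TRUE)
  expect_equal(length(at$res), 100L)
  expect_equal(sqrt(sum((clash$xyz[20, "CA", ] - clash$xyz[5, "CA", ])^2)), 2.9,
               tolerance = 1e-9)
  rep1 <- clashscore(clash)
  expect_equal(rep1$n_overlaps, brute_clash_count(clash))
  expect_equal(rep1$n_overlaps, 1L)
  expect_equal(rep1$clashscore, 10)
})

test_that("clashscore is invariant under rigid motion and atom-order irrelevant", {
  toy <- make_toy_native(22, "mixed", seed = 12)
  dec <- make_decoy_set(toy$structure, 1, 3, seed = 13)[[1]]
  r1 <- clashscore(dec)
  r2 <- clashscore(apply_rigid_motion_structure(dec, seed = 14))
  expect_equal(r1$n_overlaps, r2$n_overlaps)
  expect_equal(r1$n_overlaps, brute_clash_count(dec))
})

test_that("the pair-overlap threshold is strict at 0.4 A", {
  mk <- function(gap) {
    s <- build_from_torsions(strrep("G", 25), ref_tor(25, c(-150, 150, 180)))
    shift <- s$xyz[20, "CA", ] - s$xyz[5, "CA", ] - c(0, 0, gap)
    s$xyz[20, , ] <- sweep(s$xyz[20, , ], 2, shift)
    s
  }
  # carbon-carbon vdW sum is 3.4: overlap 0.5 at 2.9 A, only 0.3 at 3.1 A
  expect_equal(clashscore(mk(2.9))$n_overlaps, 1L)
  expect_equal(clashscore(mk(3.1))$n_overlaps, 0L)
})

test_that("clash extension deltas cover exactly the five prescribed lengths", {
  seq101 <- strrep("A", 101)
  lib <- extended_only_library(seq101)
  sch <- allocate_cycles(12, 101)
  run <- fold_sequential(seq101, lib, sch, "forward", seed = 1)
  # extended intermediates stay extended: all five deltas vanish
  cd <- clash_extension_delta(run)
  expect_length(cd$deltas, 5L)
  expect_equal(unname(cd$deltas), rep(0, 5))
  expect_equal(cd$mean_delta, 0)

  # a folded run: still exactly five differences, averaged
  lib2 <- make_idealized_library(seq101, 9, 4, 15, seed = 2)
  run2 <- fold_sequential(seq101, lib2, allocate_cycles(40, 101), "forward", seed = 3)
  cd2 <- clash_extension_delta(run2)
  expect_length(cd2$deltas, 5L)
  expect_equal(cd2$mean_delta, mean(cd2$deltas))

  # short chains lack the required intermediates
  short <- fold_sequential(strrep("A", 30),
                           make_idealized_library(strrep("A", 30), 9, 4, 15, seed = 4),
                           allocate_cycles(12, 30), "forward", seed = 5)
  expect_error(clash_extension_delta(short), "length 36")
})

test_that("ALR is antisymmetric under chain reversal and flags contact-free chains", {
  toy <- make_toy_native(30, "helix-bundle", seed = 15)
  a <- alr(toy$structure)
  n <- n_residues(toy$structure)
  reversed <- fold_structure(rev(toy$structure$sequence),
                             toy$structure$xyz[n:1, , , drop = FALSE])
  b <- alr(reversed)
  expect_equal(a$alr, -b$alr, tolerance = 1e-12)

  ext <- alr(ideal_extended(30))
  expect_true(ext$no_contacts)
  expect_equal(ext$alr, 0)
  expect_error(alr(ideal_extended(10)), "too short")
})

test_that("ALR matches a hand count on a concentrated-contact fixture", {
  # residues 16..20 hover above residues 1..3; every other residue is far
  # away. The only long-range contacts are the 5 x 3 pairs, so
  # p = 3 for residues 16..20, s = 5 for residues 1..3 and
  # ALR = (5 log2(3.5/0.5) + 3 log2(0.5/5.5)) / 8 > 0.
  ca <- matrix(0, 25, 3)
  ca[1:3, 1] <- c(0, 3.8, 7.6)
  ca[4:15, 1] <- 60 + 10 * (0:11)
  theta <- 2 * pi * (0:4) / 5
  ca[16:20, ] <- cbind(3.8 + 1.5 * cos(theta), 1.5 * sin(theta), 5)
  ca[21:25, 1] <- -60 - 10 * (0:4)
  xyz <- array(0, dim = c(25, 4, 3))
  xyz[, 2, ] <- ca
  xyz[, 1, ] <- ca + rep(c(-1.2, 0.3, 0), each = 25)
  xyz[, 3, ] <- ca + rep(c(1.2, 0.3, 0), each = 25)
  xyz[, 4, ] <- ca + rep(c(1.4, 1.4, 0), each = 25)
  s <- fold_structure(strrep("A", 25), xyz)
  st <- alr(s)
  expect_equal(st$previous[16:20], rep(3, 5))
  expect_equal(st$subsequent[1:3], rep(5, 3))
  expect_equal(st$n_contributing, 8L)
  expect_equal(st$alr, (5 * log2(3.5 / 0.5) + 3 * log2(0.5 / 5.5)) / 8,
               tolerance = 1e-12)
  expect_gt(st$alr, 0)
})
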