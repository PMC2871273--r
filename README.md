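# cotransfold

Proteins are synthesised vectorially: the ribosome extrudes the nascent chain
N-terminus first, and parts of the chain can fold before synthesis finishes.
`cotransfold` is an R package for asking what that directionality does to
fragment-assembly structure prediction. It implements a sequential Monte Carlo
folding engine that grows a backbone in nine-residue extrusions and anneals
the extruded chain after each extension — following the sense of translation
(N→C), the reverse sense (C→N), or not at all (non-sequential folding from a
fully extended chain) — together with the complete evaluation and paired
statistical machinery needed to compare the three regimes, and packaged
transcriptions of a published 68-protein directionality benchmark.

It is aimed at structural bioinformaticians and method developers who want a
small, fully deterministic, dependency-light sandbox for cotranslational
folding protocols, not at people who need CASP-grade predictions: the energy
function is a coarse backbone surrogate, and the engine runs at desk scale.

## The core quantities

**Cycle budget.** All modes share one budget. For base cycles *b* and chain
length *l*, the total number of attempted fragment insertions is
*t* = *b*·(*l*/100). Sequential runs distribute it over *e* = ⌈*l*/9⌉
extrusions: *n* = ⌊*t*/*e*⌋ cycles for each of the first *e* − 1 stages and
*t* − *n*(*e* − 1) for the last. Newly extruded residues enter in the fully
extended conformation (φ = −150°, ψ = 150°, ω = 180°).

**Model quality.** GDT_TS = 100·(N₁ + N₂ + N₄ + N₈)/(4N), where N_c is the
largest number of residues whose Cα atoms can be placed within *c* Å of their
native positions under one rigid superposition. The superposition search is
exhaustive (subset enumeration) for chains of ≤ 12 residues and a
deterministic seed-and-refine heuristic beyond. Local quality uses 11-residue
sliding windows, each independently superposed, with the mean residual Cα–Cα
distance assigned to the centre residue.

**Directionality statistics.** Per-protein mean and maximum GDT_TS for the
forward, reverse, and non-sequential algorithms are compared pairwise by
win/loss/tie counts with an exact two-sided sign test. Supporting metrics
include a van-der-Waals clashscore (overlaps > 0.4 Å per 1000 atoms), a
previous-contact bias statistic (ALR: the mean log₂ ratio of contacts to
earlier- versus later-synthesised residues), and secondary-structure-aware
terminus trimming.

## Worked example

Fold a 24-residue synthetic β-hairpin in both senses under a shared schedule
and score the results against the native:

```r
library(cotransfold)

toy <- make_toy_native(24, "hairpin", seed = 7)
assign_ss(toy$structure)$labels
#> [1] "CCCCCCEEEEECCEEEEECCCCCC"

lib <- make_idealized_library(toy$sequence, per_position = 20, noise_deg = 15, seed = 8)
allocate_cycles(200, 24)
#> <folding_schedule> l=24 b=200: t=48 cycles over e=3 extrusions (16 + final 16)

fwd <- fold_sequential(toy$sequence, lib, allocate_cycles(200, 24), "forward", seed = 1)
rev <- fold_sequential(toy$sequence, lib, allocate_cycles(200, 24), "reverse", seed = 1)
gdt_ts(fwd$final, toy$structure)
#> <gdt_result> N=24  N1=7 N2=9 N4=15 N8=20  GDT_TS=53.12
gdt_ts(rev$final, toy$structure)
#> <gdt_result> N=24  N1=7 N2=13 N4=13 N8=15  GDT_TS=50.00
```

Here 15 of 24 residues of the forward decoy superpose within 4 Å of the
native, giving GDT_TS 53.1 against 50.0 for the reverse decoy; one seed is an
anecdote, which is why `run_directional_experiment()` folds whole decoy sets
per sense and tabulates paired wins. On the packaged benchmark tables the same
comparison machinery gives:

```r
pairwise_counts(load_results("positive"), "mean", "saint", "reverse")
#> <pairwise_summary> mean GDT_TS: saint 32 / reverse 2 / ties 0  (sign test p = 6.94e-08 ***)
directionality_headline()
#> [1] 94
```

i.e. the N→C sequential algorithm beats its C→N mirror on mean GDT_TS for 32
of 34 proteins in each benchmark set — 94% of the pooled 68.

A command-line wrapper is installed at `inst/cli/cotransfold.R` with
`fold`, `eval`, `compare`, `synth` and `experiment` subcommands; every run
writes a reproducibility manifest.

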