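---
title: "Cotranslational fragment assembly: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cotranslational fragment assembly: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotransfold)
```

# The question and the design

A nascent polypeptide emerges from the ribosome N-terminus first and can
begin folding before it is complete. If that matters for structure
prediction, a fragment-assembly search that grows the chain in the sense of
translation should behave measurably differently from one that grows it in
the reverse sense — and because stochastic prediction is noisy, the fair way
to ask is a paired comparison: fold the *same* target with the *same* cycle
budget and fragment library in both senses, many times, and count per-target
wins on a quality score. `cotransfold` implements that design end to end:
the growing-chain engine, the shared budget arithmetic, the scoring, the
pairing statistics, and synthetic targets small enough that the whole
experiment runs on one CPU in minutes.

Three folding regimes share one Metropolis annealer:

* **forward sequential** — start from the first nine residues in fully
  extended conformation, anneal, append the next nine extended residues at
  the C-terminus, anneal the whole extruded chain, and so on (the final
  extrusion carries whatever remains, 1–9 residues);
* **reverse sequential** — identical, but the chain grows at the N-terminus,
  starting from the *last* nine residues;
* **non-sequential** — the full-length chain is built extended and annealed
  in a single stage.

# Cycle allocation

A *cycle* is one attempted fragment insertion. For base cycles `b` and chain
length `l`, the total is `t = round(b * l / 100)` — longer chains get
proportionally more search, mirroring the longer synthesis time they enjoy in
the cell. Sequential modes split `t` over `e = ceiling(l / 9)` extrusions as
`n = floor(t / e)` cycles per stage with the remainder `t - n * (e - 1)`
folded into the final stage, so every mode consumes exactly `t` trials (the
engine asserts this with a counter). `b` is dimensionless per 100 residues;
the historical full-scale value is 34,000, while the packaged experiments use
`b = 200`, which is enough for the toy energy landscape below.

Rounding of non-integer `t` is half-up to the nearest integer; the
documented 1.43 scaling example is integral either way.

# The backbone model

Chains carry four backbone atoms per residue (N, CA, C, O) plus a
geometrically placed pseudo-Cβ for non-glycine residues. Construction from
(φ, ψ, ω) torsions uses fixed ideal covalent geometry (N–CA 1.458 Å,
CA–C 1.525 Å, C–N 1.329 Å, C–O 1.231 Å; angles 111.2°/116.2°/121.7°, carbonyl
O anti to the next amide N), so a conformation is exactly a torsion matrix:
build-then-extract round-trips to numerical precision, which is what makes
the engine seedable and testable. The cost is that experimental structures
read from PDB files lose their non-ideal geometry if rebuilt; the folding
drivers therefore only ever operate on chains the package itself built, and
`read_pdb()` structures are used for scoring, not folding. Extension at
either terminus is a geometric continuation of the existing frame, so it
provably never perturbs existing torsions.

Fragment insertion overwrites φ and ψ across its window and the window's
*internal* peptide ω angles; the junction ω to the residue after the window
is preserved. This convention (rather than overwriting all k ω's) is what
makes a window insertion exactly mirror-symmetric between the two senses —
see the equivalence oracle below — and is physically inert, since ω stays
within a few degrees of 180 throughout.

# Fragment libraries

Without a fragment-picker database, candidates come from two sources:

* `make_idealized_library()` draws, per window, from four canonical motifs —
  helix (−57, −47), strand (−120, 130), polyproline II (−75, 145), extended
  (−150, 150) — with Gaussian φ/ψ noise (default σ = 15°, enough to blur
  motifs without destroying them) and ω ~ N(180°, σ/10). Motif weights are
  biased by a coarse per-residue propensity table (helix formers A/E/L/M/Q/K/
  R/H, strand formers V/I/Y/F/W/T/C, P strongly polyproline). The library is
  a pure function of its seed.
* `harvest_library()` cuts fully-defined torsion windows out of supplied
  structures and ranks them per target window by a BLOSUM62 similarity sum.
  Self-harvesting from the target's own experimental structure is possible
  but deliberately not done anywhere in the package's experiments: fragments
  drawn from the answer make the search homology-assisted rather than
  ab initio.

Nine-mers are the extrusion-matched default; 3-mers are supported for
refinement moves but no packaged protocol uses them.

# The annealer and its conventions

Each stage runs a fixed number of Metropolis trials over a geometric
temperature ladder (default 2.0 → 0.25 in energy units per stage; a fresh
ladder per stage). Three conventions are deliberate and worth stating:

* **Three uniform draws per trial** (window, candidate, acceptance), drawn
  whether or not the acceptance draw is needed. This keeps random streams
  aligned between runs that differ only in energies, so paired comparisons
  share their proposal sequences.
* **Window enumeration is anchored at the oldest extruded residue** —
  ascending starts for forward growth, descending for reverse. The choice
  among windows is uniform either way (this changes nothing in
  distribution), but it makes trial *i* of a reverse run propose the exact
  mirror of trial *i* of the corresponding forward run under a shared seed.
* **Best-so-far carry-over**: the conformation passed to the next extrusion
  is the lowest-energy conformation visited during the stage, not the last
  accepted one. "The conformation reached" by an annealing stage is
  ambiguous; best-so-far is the variant that makes the stage result
  monotone in energy (asserted in the tests), and switching to last-accepted
  would be a one-line change.

These conventions enable an exact engine oracle: folding a sequence in
reverse is trajectory-identical (in torsion space, to 1e-9°) to folding the
reversed sequence forward with a mirrored library (φ/ψ swapped, window order
reversed), a mirrored extension conformation (150, −150, 180), and any energy
that is a symmetric function of the torsion multiset. The test suite runs
this equivalence on an 18-residue random sequence. With the *physical*
energy the equivalence is broken — deliberately, since the peptide backbone
is chemically directional (N–CA ≠ C–N), which is part of what the experiment
probes.

# The energy surrogate

`chain_energy()` is a coarse stand-in for a fragment-assembly score
function, with four terms: soft-sphere repulsion (squared van-der-Waals
overlap over nonbonded backbone + pseudo-Cβ pairs), a compactness term (Cα
radius of gyration over the globular expectation 2.2·n^0.38 Å), a backbone
hydrogen-bond reward (Kabsch–Sander electrostatic criterion, −0.5 kcal/mol
cutoff), and a torsion-propensity penalty (squared distance to the nearest
motif basin, capped). Default weights (1, 1, 0.5, 0.25) were chosen once so
that no single term dominates on 20–30-residue toys; they are exposed, not
tuned per target. The function is monotone where it must be — adding a hard
clash strictly raises it, expanding a compact chain raises the compactness
term — and nothing more is claimed for it. In particular, absolute GDT_TS
levels reached with this surrogate say nothing about what a full-physics
score function would reach; only *paired differences* between senses are
meaningful, and even those only for the toy landscape.

# Evaluation

**GDT_TS.** For chains of ≤ 12 residues the per-cutoff counts are exact:
every residue subset of size ≥ 3 is used as a superposition frame and the
best inlier count kept. Beyond that, a deterministic seed-and-refine
heuristic is used: seeds from every contiguous segment of lengths 4, 8, 16
and the whole chain, each walked down a cutoff ladder (4c, 2c, c) with
iterative refitting on inliers (≤ 10 rounds per rung, fit kept alive on the
3 closest residues when inliers run short). The heuristic can only
undercount, never overcount; on structured small cases it matches the exact
search, and the suite asserts it never falls below a naive whole-chain
superposition. Counts are forced cumulative across cutoffs. Exhaustive
equality on *arbitrary* noisy small chains is not attainable for any
seeded-refinement scheme — the optimal inlier subsets can be non-contiguous —
which is exactly why the small-chain path is exact instead.

**Local window quality.** Every 11-residue window is superposed
independently (the local-frame reading of window alignment; a global-frame
variant would conflate local and global error). Mean residual Cα–Cα distance
goes to the centre residue; the per-class sense difference averages these
over natively helical (or strand) residues, then over each decoy set, and
reports reverse-mean minus forward-mean, so positive values favour the sense
of translation. Targets with no strand residues return `NA` for the strand
class and are excluded from strand analyses.

**Terminus trimming.** Models are cut back to the span from the first to the
last native secondary-structure element (a run of ≥ 4 identical H or E
labels; coil runs are not elements — trimming to a coil "element" would be
meaningless). The two terminal elements must span at least five residues
counted inclusively from the end of the first to the start of the last;
shorter spans skip the protein untrimmed, with a message. This inclusive
reading is the one consistent with both boundary examples exercised in the
tests.

**Clashscore.** Overlaps > 0.4 Å between atom pairs more than three covalent
bonds apart, per 1000 atoms, with radii C 1.70 / N 1.55 / O 1.52 Å. The
exclusion includes 1-4 pairs: in ideal trans-peptide geometry the
O(i)···CA(i+1) 1-4 distance is ≈ 2.77 Å against a 3.22 Å radius sum, so any
rule that counts 1-4 pairs brands every peptide bond a permanent clash and
no chain could ever score zero. With the standard exclusion, extended chains
and the tuned toy natives are exactly clash-free. The blind-extension
protocol measures the clashscore change when nine extended residues are
appended at the growing terminus of the folded intermediates of lengths 18,
36, 54, 72 and 90, and averages the five differences. Absolute clashscores
from this backbone + pseudo-Cβ model are not comparable to all-atom,
hydrogen-added scores; only differences carry signal.

**Previous-contact bias (ALR).** A contact is a Cα pair within 8 Å at
sequence separation ≥ 5. For residue *i* with `p` contacts to earlier and
`s` to later residues, the statistic is the mean of
`log2((p + 1/2)/(s + 1/2))` over residues with at least one long-range
contact (½ as a pseudo-count, log base 2 for symmetric units); chains with
no long-range contact report 0 with a flag. The definition is antisymmetric
under index reversal by construction. It is *this package's* concrete
instantiation of a previous-contact measure: per-protein values in the
packaged tables were computed with the original authors' implementation and
are not expected to be numerically reproduced by this one, so the package
never recomputes table ALR values, only uses them as row metadata.

# The packaged benchmark tables

Four TSV fixtures transcribe the published per-protein results of the
directionality benchmark: mean and maximum GDT_TS per algorithm for 34
proteins with strong previous-contact bias (ALR ≥ 0.15) and 34 with the
opposite bias (ALR ≤ −0.15), plus the terminus-trimmed maxima (the trimmed
positive-set table has 33 rows; one protein has no printed entry, consistent
with the trimming eligibility rule). Transcription is guarded by an MD5
checksum at load time, and every quoted summary — win counts, set means,
extreme gaps, satisfactory-prediction counts, the pooled directionality
percentage — is recomputed from the rows rather than stored. Where a derived
summary of the printed rows disagrees with a summary quoted alongside them
in the source (it happens for one set-level mean, one max-GDT win tally and
one tie count, each by one unit or one hundredth), the package reports the
value computed from the rows: the tables are the data, prose summaries are
derived. The tests pin the table-derived values.

The sign test behind the win/loss summaries is the exact two-sided binomial
test on informative (non-tied) pairs, with conventional significance stars;
ties are exact equality at the tables' printed two-decimal precision.

# Synthetic targets: what they do and do not emulate

`make_toy_native()` builds clash-free single-domain folds from tuned torsion
recipes — an α-helix, a two-stranded antiparallel β-hairpin whose
Kabsch–Sander ladder is genuinely hydrogen-bonded, a two-helix bundle, and a
mixed helix + hairpin topology — with optional torsion jitter (clash-freedom
enforced by seeded retries). Decoy sets for metric testing perturb the
native in torsion space, with the perturbation amplitude bisected per decoy
so the post-superposition Cα RMSD lands on the requested σ; torsion-space
noise keeps every decoy a valid chain, which Cartesian noise would not.

These toys exercise every code path — extrusion, annealing, assignment,
scoring, pairing — but they are 20–30 residues, have designed (not evolved)
sequences, and live on a surrogate energy landscape. A directional
experiment on them (`run_directional_experiment()`: 5 targets, `b = 200`,
20 decoys per sense, deterministic per seed, about two minutes) demonstrates
the pipeline and reports whatever the simplified engine yields; no claim is
made that its win rate reproduces the benchmark's 94%, and the package
nowhere asserts that it should. Reproducing the benchmark's absolute
per-protein GDT_TS values would require the original full-scale search
engine, its fragment database and thousands of decoys per protein, all out
of scope here.

# Numerical choices and degenerate inputs

* Angles live in (−180°, 180]; wrap-around is applied before any comparison.
* Torsion round-trips are asserted to 0.5° in contracts but hold to ~1e-13°.
* Undefined terminal torsions (φ₁, ψₙ, ωₙ) are `NA` on extraction; rebuilding
  uses extended-conformation placeholders, and the engine tracks its own
  concrete torsion state so placeholders never leak into trajectories.
* Single-residue chains have no dihedrals (error); chains under 5 residues
  assign all-coil with a warning; empty eligible-window sets are an error
  unless the stage has zero cycles, which is the identity.
* Ties in fragment-harvest ranking break by source order; ties in "best
  decoy" selection break by lowest decoy index; `which.max` semantics give
  first-occurrence ties in extreme-difference reports.
* Per-decoy seeds are `base_seed + i`, so decoy sets are reproducible in any
  execution order; all drivers restore the caller's RNG state.

# Known limitations

The energy surrogate has no solvation, no side chains beyond pseudo-Cβ and
no pair-specific contact potential; secondary-structure assignment is
three-state and simplified around bulges and chain breaks; the GDT heuristic
can undercount tight cutoffs on highly distorted chains (bounded below by
the whole-chain fit, bounded above by the exact search it hands over to on
small chains); PDB input is single-chain, standard-residue, complete-backbone
only. The ribosome exit tunnel, variable translation speed and variable
extrusion sizes are not modelled; the extrusion schedule is the only
cotranslational ingredient.
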