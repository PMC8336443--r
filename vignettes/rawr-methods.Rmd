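---
title: "Random walk resampling for phylogenetic support: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random walk resampling for phylogenetic support: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rawr)
```

## The problem

Phylogenetic bootstrap support treats the columns of a multiple sequence
alignment (MSA) as independent and identically distributed observations:
replicates are drawn by sampling columns i.i.d. with replacement, a tree is
re-estimated on each replicate, and the support of a branch of the
annotation tree (the tree estimated on the original data) is the fraction of
re-estimated trees displaying its bipartition. Real sequences violate the
i.i.d. assumption — most visibly through insertion and deletion processes —
and bootstrap replicates destroy the adjacency structure that makes
re-alignment meaningful.

Random walk resampling (RAWR) replaces i.i.d. column sampling with a
reversal random walk over the columns of the annotation MSA. Because the
walk moves one column at a time, every pair of adjacent sites in a replicate
was adjacent in the source alignment (*neighbor preservation*), so the
replicate can be unaligned (gaps dropped) and meaningfully re-aligned before
tree re-estimation. Support calculation is unchanged; what changes is what a
replicate is, and that both the MSA and the tree are re-estimated on it.

## The reversal walk

Given an alignment with $L$ columns and a reversal probability
$\gamma \in [0,1]$:

1. choose a start column uniformly on $\{1,\dots,L\}$ and a direction
   uniformly from $\{\text{left},\text{right}\}$;
2. sample the current column;
3. reverse direction with probability $\gamma$; then apply boundary
   reflection to the resulting direction (a walk standing at column $1$
   facing left, or at column $L$ facing right, reverses with certainty);
4. move one column in the current direction;
5. stop when $L$ columns have been sampled (sequence-length convergence),
   then unalign the sampled columns, preserving walk order.

Two details deserve comment.

**Boundary semantics.** Reflection is applied to the *post-draw* direction.
A literal "reverse if the draw succeeds OR the walk faces outward at a
boundary" has one reachable state with no valid move: standing at the last
column facing inward, a successful draw would turn the walk outward and off
the alignment. Composing draw-then-reflection agrees with the OR rule in
every other state, never consumes a second draw, and is the standard
construction of a reflecting walk. At $\gamma = 1$ the walk oscillates
between two adjacent columns.

**Edge-column bias.** Reflection makes aggregate column sampling non-uniform
at exactly the two boundary columns: over one period of the walk the
boundary column is visited once while interior columns are visited twice, so
its long-run sampling frequency is $1/2$ of the interior frequency. Interior
columns are near-uniform in aggregate because start columns are uniform
(measured: maximum interior deviation below 10% at $L = 50$,
$\gamma = 0.1$, 5000 walks). This bias is inherent to certain reflection,
affects two of $L$ columns, and is averaged over in support estimation; the
teleportation variant removes it.

With $\gamma = 0$ the walk is the deterministic mirrored sweep from a random
start; with $0 < \gamma < 0.5$ it is a second-order Markov process on
(column, direction) states that preserves progressively less long-range
adjacency as $\gamma$ grows. The study grid for $\gamma$ is
$\{10^{-3}, 10^{-2}, 2\times10^{-2}, 5\times10^{-2}, 10^{-1}, 2\times10^{-1},
3\times10^{-1}\}$ with default $\gamma = 0.1$; smaller values preserve more
sequential dependence, larger values inject more re-alignment noise around
reversal breakpoints.

**Teleportation variant.** With probability $\gamma$, instead of reversing,
the walk restarts at a uniform column and direction. Segments between
teleports retain neighbor preservation; at $\gamma = 1$ every sample is an
independent uniform draw, making the variant a continuum between RAWR and
bootstrap.

**Replicate streams.** `resample_many()` derives one RNG stream per
replicate from a master seed (`set.seed(master)` followed by one
`sample.int` draw of per-replicate seeds), so a replicate set is exactly
reproducible and individual replicates are independent of $k$.

## Support estimation

`rawr_support()` composes the full pipeline: annotation alignment
$A = f(\text{seqs})$, annotation tree $T = g(A)$, then for each replicate
$X_i$ (unaligned walk sample of $A$'s columns), $T_i = g(f(X_i))$. Support
of each non-trivial bipartition of $T$ is the fraction of $T_i$ displaying
it — always an exact multiple of $1/k$. Bipartitions are canonicalized as
the side not containing the lexicographically smallest taxon, making
equality invariant to rooting and taxon order. `bootstrap_support()` uses
i.i.d. column resampling and re-estimates only trees: re-aligning a
bootstrap replicate is not meaningful precisely because adjacency (and with
it local homology) is destroyed.

The study protocol uses $k = 100$ replicates; `k = 10` is the reduced
protocol ("RAWR-reduced"), which trades a small amount of support
resolution for an order of magnitude less re-estimation work.

Replicate failures abort the analysis by default; `on_error = "skip"` drops
the failing replicate with a warning and renormalizes by the number of
successful re-estimates, so the support denominator is always explicit.

**Multi-locus protocol.** For partitioned data, each replicate independently
resamples each partition's columns with a reversal walk, *keeps the columns
aligned* (no unalign/re-align step, mirroring how partitioned re-estimation
is run in practice), drops partitions missing any of the four nucleotides
(avoiding degenerate per-partition model fits), concatenates the survivors
into a supermatrix, and re-estimates a tree on it. Support is computed
against the annotation tree estimated on the full concatenation. The
per-partition $\gamma$ default is the single-locus default, 0.1.

## Built-in re-estimation backends

The package's contribution is resampling, not alignment or tree search, so
the built-in backends are deliberately simple, deterministic stand-ins that
make the full pipeline self-contained:

- `builtin_align()` — progressive alignment: normalized shared 4-mer
  distances, neighbor-joining guide tree (midpoint-rooted), bottom-up
  profile–profile global Needleman–Wunsch with match $+2$, mismatch $-1$,
  linear gap $-2$ (C++ kernel; ties broken diagonal, then gap-in-second,
  then gap-in-first). Zero-length sequences become all-gap rows.
- `builtin_tree()` — neighbor joining on Jukes–Cantor-corrected distances
  with pairwise gap deletion. Saturated or undefined distances (no shared
  ungapped sites, or mismatch fraction $\ge 3/4$) are capped at 5
  substitutions per site. Three taxa give the star tree; all-gap taxa are
  rejected with advice to length-filter first, rather than being placed
  arbitrarily.

Maximum-likelihood re-estimation is delegated to external adapters (MAFFT
for alignment; FastTree and RAxML for trees) behind the same contracts:
aligners must preserve the taxon set and satisfy unalign–of–align identity,
tree estimators must return the input taxa. `align()` and `infer_tree()`
enforce both contracts for every backend.

## Synthetic benchmarks

`make_condition_fixtures()` emulates the benchmark design: a model condition
is (number of taxa, tree height, indel rate), with 1 kb root sequences and
20 replicates by default.

- **Model trees** grow by uniform random leaf splitting (a random birth
  process); every branch length is Uniform(0,1) and all are rescaled so the
  maximum root-to-leaf path equals the condition height exactly. Trees are
  non-ultrametric by construction.
- **Substitutions** follow a GTR matrix scaled to one expected substitution
  per unit branch length at stationarity (Jukes–Cantor by default; arbitrary
  frequencies/exchangeabilities accepted; optional 4-category discrete-gamma
  rate variation). Transition matrices come from the eigendecomposition of
  the reversible rate matrix.
- **Indels**: on a branch of length $t$, each site is deleted with
  probability $1 - e^{-rt}$ and each inter-site junction receives an
  insertion with the same probability, with geometric lengths (mean 2) and
  stationary residues. The benchmark's single "indel probability" is applied
  as both the insertion and the deletion rate $r$. This is a simplification
  of full indel-simulator machinery, chosen so the rate interacts with
  branch length the same way substitutions do.
- **Homology tracking** is exact: every residue carries a global real-valued
  column coordinate (root sites at integers; insertions draw fresh
  coordinates inside the host interval, with collisions excluded by a
  registry), so the true alignment of all surviving residues is recovered
  by sorting coordinates, and `unalign(true_alignment)` equals the leaf
  sequences identically.

What the simulator does *not* capture: selection and secondary-structure
constraints, empirically calibrated indel length spectra, rate variation
beyond discrete gamma, and recombination. Passing tests on these benchmarks
therefore demonstrate correctness of the machinery and the direction of
method differences, not empirical effect sizes on real data.

## Evaluation metrics

- **Confusion classes** at threshold $t$ over the estimated tree's
  non-trivial bipartitions, with the positive rule *support $\ge t$* and
  reference membership deciding true/false. The four counts always sum to
  the number of estimated bipartitions.
- **PR curve / PR-AUC**: thresholds sweep the sorted unique support values;
  precision $TP/(TP+FP)$, recall $TP/(TP+FN)$; a sentinel threshold above
  the maximum contributes the conventional (recall 0, precision 1) endpoint;
  AUC is the trapezoidal integral over recall-ordered points. Aggregate
  PR-AUC across datasets pools confusion counts at each threshold before
  computing precision/recall (a mean-of-AUCs alternative is exposed as
  `method = "mean"`; pooling is the default because a single aggregate
  curve weights every bipartition equally rather than every dataset).
- **nRF**: symmetric difference of non-trivial bipartition sets divided by
  the total count across both trees ($2(n-3)$ for binary trees).
- **SP-FN / SP-FP**: proportions of residue-pair homologies (pairs of
  residues sharing a column) present in the truth but not the estimate, and
  vice versa. Both alignments must carry identical unaligned sequences.
- **ANHD**: mean pairwise mismatch proportion; sites gapped in either row of
  a pair are excluded from numerator and denominator (stated here because
  the gap convention is not universal — printed ANHD values from other
  pipelines are not directly comparable), and any comparison involving `N`
  counts as a mismatch. Pairs with no comparable sites are excluded with a
  warning.
- **Gappiness**: gap cells over matrix cells.

## Numerical and interface conventions

- All coordinates are 1-based inclusive (native R), including walk traces
  and partition intervals; the RAxML partition dialect is itself 1-based
  inclusive so no conversion occurs at the boundary.
- The alphabet is `A C G T N -`; IUPAC ambiguity codes collapse to `N` on
  read, `.` is rejected as a gap character, and `N` never matches anything
  (including `N`).
- Empty (all-gap) taxa are retained by resampling — dropping them silently
  would corrupt support bookkeeping over a fixed taxon set — and rejected
  explicitly by tree estimation.
- Everything downstream of a seed is deterministic, including the built-in
  backends; experiment reports are reproducible from their configuration
  alone.

## Problem sizes used in the test suite

The packaged experiments are sized for a single CPU: the method-comparison
experiment uses one 10-taxon condition (height 0.7, indel rate 0.1, 1 kb
roots, 10 datasets, $k = 20$), parameter recovery uses 20 low-divergence
datasets (height 0.1), and walk-law checks enumerate complete traces
exhaustively at $L \le 4$. These sizes were chosen as the smallest at which
the method contrasts are stable across seeds; the protocol scales to the
full study design ($k = 100$, 20 datasets per condition, external ML
backends) by configuration only.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
tree <- sample_model_tree(n_taxa = 10, height = 0.5)
sim <- evolve_sequences(tree, gtr_params(insertion_rate = 0.1,
                                         deletion_rate = 0.1),
                        root_length = 500)
res <- rawr_support(sim$seqs, k = 20, seed = 7)
res$support
pr_curve(res$tree, res$support, ape::unroot(sim$tree))$auc
```

## Known limitations

- The built-in backends are distance-based and progressive; they are weaker
  than MAFFT/RAxML, so absolute PR-AUC values on the packaged benchmarks sit
  below what external ML backends produce. Method *contrasts* (RAWR vs
  bootstrap) are the supported comparison.
- The walk's boundary columns are undersampled by a factor of two (see
  above); analyses for which the terminal alignment columns are critical
  should prefer the teleportation variant.
- The multi-locus protocol resamples within partitions and does not model
  gene-tree discordance across loci.
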