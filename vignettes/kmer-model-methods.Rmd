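---
title: "Linear k-mer models for SELEX reads: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear k-mer models for SELEX reads: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexkmer)
```

This vignette is the package's own account of the statistical model it
implements, the tunable parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
that were genuinely open.

## The model and its assumptions

A sequence's predicted binding affinity is the sum of the affinities of the
k-mers it contains. Training data are two read sets: *bound* reads from a
SELEX enrichment cycle and *unbound* uniform random reads. The design matrix
`A` has one row per read and one column per feature k-mer, with `A[i, j] = 1`
iff k-mer *j* occurs in read *i*; the response `b` is 1 for bound reads and 0
for unbound ones. The affinity vector solves the ridge-stabilized
least-squares problem `min ||Ax - b||^2 + lambda ||x||^2`.

Assumptions worth keeping in mind:

* **Binary presence, not occupancy.** A k-mer occurring twice in a read
  contributes once. This matches the training semantics exactly at scoring
  time (a training read's score is its row of `A x`); an occurrence-weighted
  scorer exists (`score_sequences(..., occurrence = TRUE)`) for exploration
  only.
* **Equally weighted reads.** Every bound read counts the same even though
  true per-read affinity varies; with deep sequencing, strongly bound k-mers
  compensate by appearing in more reads.
* **Both strands, one feature.** Binding is detected on either strand, so a
  k-mer and its reverse complement are merged into one *canonical* feature
  (the lexicographically smaller of the pair). Keeping them as two features
  would make the corresponding columns of `A` identical and the normal
  equations singular; merging is the package default and the reason every
  score in the package is strand symmetric.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `k` (word lengths) | 4–8 | feature vocabulary; mixed lengths are allowed because informative words can be longer (hence rarer) than the bulk of frequent short words |
| `ridge_lambda` | 1e-6 | numerical conditioning only; see below for when a larger value is appropriate |
| `n_kmers` / criterion | 100, most frequent | size and ranking of the feature set |
| `train_fraction` | 0.7 | the conventional 7:3 train/test split |
| `folds` | 10 | CV folds in backward elimination |
| `alpha` | 0.05 | all intervals are 95% intervals |

The word-length range is a package choice: nothing in the modelling framework
pins down a single k, and the default 4–8 covers typical eukaryotic core
motifs while keeping the canonical vocabulary manageable.

**On the ridge penalty.** With `lambda = 1e-6` the fit is numerically a
pseudoinverse: it exists even when feature columns are collinear (k-mers that
always co-occur), and the fitted values `A x` are essentially the
unregularized least-squares fit. For *interpreting individual affinities*,
however, the minimum-norm solution deliberately spreads weight across
near-collinear columns — a planted consensus, its shifted overlaps and its
one-base extensions share the signal, and sampling noise can reorder them.
When the analysis question is "which single k-mer carries the largest
affinity?" (as in the consensus-recovery analysis of `scripts/acceptance.R`),
a unit ridge (`lambda = 1`) damps that noise-driven splitting and makes the
affinity ranking stable without visibly changing classification accuracy:
the Gram matrix diagonal entries are in the thousands at these read counts,
so `lambda = 1` is still a small relative perturbation.

## Feature selection

Three strategies are implemented, all operating on the k-mer count table
(per-k-mer presence counts in bound and unbound reads):

* `frequency`: largest `count_bound + count_unbound`;
* `difference`: largest `count_bound - count_unbound`;
* `fold_change`: largest `(count_bound + c) / (count_unbound + c)`. The
  pseudocount `c = 1` is required because enriched k-mers are routinely
  absent from the unbound set; without it the ratio is undefined.

The wrapper strategy, `cv_backward_eliminate()`, starts from the most
frequent set and greedily removes one k-mer per step — the one whose removal
gives the highest mean k-fold CV accuracy. Design details that the
greedy-wrapper idea leaves open, and how this implementation resolves them:

* **Folds** are stratified by label and fixed by an explicit seed, so a
  trajectory is bit-reproducible.
* **Thresholds** are re-optimized inside each CV training fold and applied to
  that fold's held-out part; the held-out part never influences the
  threshold, and the external test set never enters the procedure at all.
  This is what protects the final test accuracy from selection bias.
* **Ties** between removal candidates are broken by removing the
  lexicographically last k-mer — an arbitrary but deterministic rule.
* The search is greedy with no re-addition; removal quality is judged by CV
  accuracy alone.

## Classification and evaluation

`optimal_threshold()` maximizes training accuracy of the rule
`score >= t ⇒ positive`. Ties are classified positive (the tie side is a
convention; it only matters for degenerate score distributions). Among
realizable thresholds the midpoint between adjacent distinct scores is
reported, and with several equally accurate cut points the first in
descending-score order is chosen — again determinism over any claim of
optimality. Accuracy CIs are Wald (normal-approximation) intervals clipped to
[0, 1].

For peak sequences the package reports the Mann–Whitney AUC — the fraction of
(positive, negative) pairs won, ties counting one half, computed via midranks
— with a normal interval using the Hanley–McNeil variance

```
var = [ A(1-A) + (n_pos - 1)(Q1 - A^2) + (n_neg - 1)(Q2 - A^2) ] / (n_pos n_neg),
Q1 = A / (2 - A),  Q2 = 2 A^2 / (1 + A).
```

Several Mann–Whitney-type interval variants exist; Hanley–McNeil is the
package's stated choice and the one its tests pin down. Peak centering uses
the sequence midpoint unless a summit offset is supplied; peaks are consumed
as pre-extracted FASTA, so genome arithmetic stays out of scope.

PWM scanning uses natural-log odds against a uniform background by default.
A PWM file with counts receives a pseudocount of 1; a frequency matrix
receives 0.01 only if it contains zeros, so positive matrices round-trip
bit-faithfully. Reads shorter than the motif are skipped with a warning
rather than padded.

## The simulator: what it emulates, and what it does not

`simulate_selex()` idealizes one SELEX round as Boltzmann selection: a
molecule survives and is re-amplified with probability proportional to
`exp(beta * affinity)`. The exponential form is the standard idealization of
affinity-proportional capture with a tunable stringency; the wet protocol
itself specifies no quantitative selection law.

One scale issue matters at desk size. In a real experiment the molecular pool
(~10^12 molecules) dwarfs the sequenced sample, so duplicate reads are rare
even in late cycles. If the selection chain is run directly on a pool the
size of the sequenced sample (a few thousand reads), the late cycles collapse
onto a handful of founder molecules, and arbitrary founder-flank k-mers
become perfect predictors of the bound label — an artifact with no wet-lab
counterpart. The simulator therefore separates the two scales: the chain runs
on an internal pool `library_factor` times larger than the sample (default
50x), and each cycle reports a `pool_size` sequencing sample from it. The
defaults — 14 nt reads, 5000 sequenced reads per cycle, 3 cycles, a single
planted consensus (the AP-1 site TGACTCA) at `beta = 3` — take the consensus
from its ~0.1% background occurrence to a clear pool majority by cycle 3,
i.e. a medium-enrichment experiment.

Deliberately **not** modelled: PCR amplification bias, sequencing errors,
non-specific carryover between cycles, and multi-protein competition. Passing
tests on these simulations therefore demonstrates correctness of the
estimation machinery under the stated selection law, not robustness to the
technical noise of real SELEX libraries.

`simulate_dependent_motif_reads()` plants exactly one of several motif
variants per read (random offset and strand). Two or more dissimilar variants
create dependencies between motif positions that a single PWM cannot
represent — the regime where the k-mer model's advantage is structural, which
is what the k-mer-versus-PWM comparison in the acceptance analyses exercises.
`simulate_peaks()` plants a motif inside the central 50 nt of otherwise
random "peak" sequences, emulating summit-proximal binding sites.

## Problem sizes in the shipped analyses

The test suite and `scripts/acceptance.R` use: 20 replicates of the
3-cycle / 5000-read recovery experiment; 5 replicates of the 4-cycle trend;
5000 reads for the two-variant PWM comparison; 2000 reads, a 40-k-mer start
set and 10-fold CV for the backward-elimination analysis; and 300 + 300 peaks
of 300 nt. These sizes give stable estimates (binomial standard errors below
one percentage point for the main accuracies) while a full run of the
analyses completes in minutes on a single core.

For the backward-elimination demonstration the vocabulary is `k = {3, 8}`:
abundant, weakly informative 3-mers versus rare, fully informative planted
8-mers. This makes the scientific point crisply — frequency ranking buries
the informative words (they rank below all 32 canonical 3-mers), while the
CV wrapper digs them out — without the combinatorial cost of a full 4–8
vocabulary inside the CV loop.

## Degenerate inputs and numerical corner cases

* Empty read sets, single-class labels, and a start set smaller than
  `min_size` are errors, not silent degradations.
* An all-zero feature column is an error at `lambda = 0` (rank deficiency)
  and shrinks to a zero affinity for `lambda > 0`.
* Underdetermined systems (more k-mers than reads) return the ridge
  minimum-norm solution with a warning.
* Windows containing `N` contribute nothing anywhere (presence counting, PWM
  scanning); reads consisting only of such windows score `NA` in PWM paths
  and are skipped with a warning by the classifiers.
* Affinities and PWM probabilities are serialized at full double precision
  (`%.17g`), so save/load round-trips are lossless.
* All stochastic functions take an explicit seed and restore the caller's
  RNG state; identical seeds give byte-identical outputs end to end.

## Known limitations

* Affinities are fit by plain least squares on binary labels; no logistic or
  count-based likelihood is offered.
* PWMs are consumed, not learned: the only PWM construction is the naive
  count matrix from aligned planted instances used as a simulation benchmark.
* The backward-elimination wrapper is O(set size squared) refits per
  trajectory and is intended for start sets of a few hundred k-mers at most.
* Peak evaluation assumes pre-extracted sequences; there is no peak calling
  and no genome/BED handling.
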