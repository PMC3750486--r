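# selexkmer

Linear k-mer models of transcription-factor binding specificity from
high-throughput SELEX reads.

## The problem

SELEX (systematic evolution of ligands by exponential enrichment) starts from
a pool that evenly represents every oligonucleotide of a fixed length
(typically 14 nt), lets the protein of interest bind its preferred sequences,
and repeats the bind–precipitate–amplify round several times. Sequencing each
enrichment cycle yields sets of *bound* reads; the modelling task is to learn,
from bound reads versus random unbound reads, a function that predicts how
well the protein binds any sequence. Position weight matrices (PWMs) are the
dominant model, but they score motif positions independently; k-mer models
assign an affinity to every word of length k and therefore capture
dependencies between neighbouring positions.

`selexkmer` is for computational biologists who want to train, select and
benchmark such models — on their own read sets or on fully simulated data with
a known planted truth.

## The model

Let `A` be the binary design matrix with one row per read and one column per
canonical k-mer (a k-mer and its reverse complement form a single feature, so
sites are detected on both strands): `A[i, j] = 1` iff k-mer *j* occurs in
read *i* on either strand. With the binary label vector `b` (1 = enriched
read, 0 = random read), the affinity vector `x` solves the least-squares
problem

```
min_x || A x - b ||^2 + lambda || x ||^2
```

with a small ridge term `lambda` for conditioning. The predicted affinity of
any sequence is the sum of the affinities of the k-mers present in it.
Because which k-mers enter the model matters as much as their weights, three
selection strategies are provided:

1. **most frequent** k-mers in the whole data,
2. **most enriched** k-mers (count difference or fold change between bound
   and unbound sets),
3. **backward elimination**: starting from the most frequent set, repeatedly
   remove the k-mer whose removal helps (or hurts least) the mean 10-fold
   cross-validation classification accuracy *within the training data* — a
   wrapper selection that never touches the external test set.

Evaluation follows standard practice: reads are split 7:3 into training and
test sets, negatives are uniform random sequences matched in number, the
classification threshold is optimized on training scores, and test accuracy
is reported with a normal-approximation 95% CI. For long ChIP-seq-style peak
sequences, where a fixed read-level threshold is not meaningful, the package
reports the Mann–Whitney AUC (the probability that a bound sequence outscores
an unbound one) with a Hanley–McNeil 95% CI, on full peak regions or on 50/100
nt windows around the peak center. PWMs in MEME minimal, JASPAR-style or
plain-matrix format can be scanned (max log-odds over windows and strands) for
head-to-head comparisons, and top k-mers can be aligned back to a motif.

A SELEX simulator supplies ground truth for all of this: a uniform initial
library, Boltzmann selection `exp(beta * affinity)` per cycle under a planted
motif model, resampling at constant pool size, and a configurable ratio
between the molecular pool and the sequenced sample.

## Worked example

Simulate a 3-cycle SELEX experiment with the AP-1 consensus `TGACTCA`
planted, then train and evaluate a 100-k-mer model on the cycle-3 reads:

```r
library(selexkmer)

sim <- simulate_selex(selex_config(seed = 7))
fit <- selex_train_test(sim$cycles$cycle3, n_kmers = 100, seed = 8)

print(fit$model)
#> linear k-mer model: 100 k-mers (k in {4, 5, 6, 7, 8}), ridge_lambda = 1e-06
#>   trained on 7000 reads, residual norm 19.63
#>   top affinities: GACTCAA=0.841, TGACTCA=0.714, ATGACTC=0.386, CTGAGTCA=0.324, GTGAGTCA=0.312

print(fit$test)
#> accuracy = 0.9323  [95% CI 0.9233, 0.9413]  (n_pos = 1500, n_neg = 1500, threshold = 0.3368)
```

The model classifies held-out cycle-3 reads against random 14-mers with 93%
accuracy, and the k-mers carrying the largest affinities are the planted
consensus and its shifted/extended variants — overlapping words that share
the binding signal. (With a stronger ridge, e.g. `ridge_lambda = 1`, the
consensus itself reliably carries the single largest weight; see the methods
vignette.) Earlier cycles are harder: the same pipeline on cycle-1 reads
scores close to chance, because one round of selection barely changes the
pool composition.

The command-line interface wraps the same functions
(`inst/cli/selexkmer.R`; subcommands `simulate`, `train`, `select-cv`,
`evaluate`, `scan-pwm`, `align-kmers`), e.g.

```sh
Rscript inst/cli/selexkmer.R simulate --out-dir sim --seed 7
Rscript inst/cli/selexkmer.R train --positives sim/cycle3.txt \
    --out-model model.tsv --out-report report.json --seed 8
```

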