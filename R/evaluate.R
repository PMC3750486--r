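## Train/test splitting, random negative sets, threshold classification with
## normal-approximation confidence intervals, and Mann-Whitney AUC with
## Hanley-McNeil confidence intervals for peak-sequence evaluation.

as_binary_labels <- function(labels) {
  if (is.logical(labels)) labels <- as.numeric(labels)
  if (!is.numeric(labels) || !all(labels %in% c(0, 1))) {
    stop("`labels` must be binary (0/1 or logical)")
  }
  labels
}

#' Split reads into training and test sets
#'
#' Random disjoint, exhaustive partition; the training set gets
#' `round(n * train_fraction)` reads (the conventional 7:3 split by default).
#'
#' @param reads Character vector (>= 2 reads).
#' @param train_fraction Fraction of reads assigned to training, in (0, 1).
#' @param seed Optional integer seed for a reproducible partition.
#' @return List with elements `train` and `test`.
#' @export
split_reads <- function(reads, train_fraction = 0.7, seed = NULL) {
  if (length(reads) < 2L) stop("need at least 2 reads to split")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)")
  }
  with_seed(seed, {
    n <- length(reads)
    n_train <- round(n * train_fraction)
    n_train <- min(max(n_train, 1L), n - 1L)
    idx <- sample.int(n, n_train)
    list(train = reads[idx], test = reads[-idx])
  })
}

#' Generate uniform random reads (the negative set)
#'
#' Draws `n` i.i.d. sequences of the given length, each base uniform over
#' `{A, C, G, T}` — the appropriate negative model when the initial SELEX
#' pool contains all words of the read length evenly.
#'
#' @param n Number of reads (>= 1).
#' @param length Read length (default 14, the standard SELEX pool length).
#' @param seed Optional integer seed.
#' @return Character vector of `n` reads.
#' @export
generate_random_reads <- function(n, length = 14, seed = NULL) {
  if (n < 1L) stop("`n` must be >= 1")
  if (length < 1L) stop("`length` must be >= 1")
  with_seed(seed, {
    m <- matrix(sample(DNA_BASES, n * length, replace = TRUE), nrow = n)
    do.call(paste0, lapply(seq_len(length), function(j) m[, j]))
  })
}

#' Optimal classification threshold on a score vector
#'
#' Finds the threshold maximizing the accuracy of the rule
#' `score >= threshold => positive` (ties classified positive). Among
#' realizable thresholds the reported value is the midpoint between the two
#' adjacent distinct scores, so the decision boundary does not sit exactly on
#' a training score. Deterministic: with several equally accurate thresholds
#' the one admitting the most positives ranks last, and the first optimum in
#' descending-score order is returned.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels aligned to `scores`; both classes required.
#' @return List with `threshold` and `accuracy` (training accuracy at that
#'   threshold).
#' @export
optimal_threshold <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) stop("`scores` and `labels` lengths differ")
  if (!all(is.finite(scores))) stop("`scores` must be finite")
  if (length(unique(labels)) < 2L) stop("`labels` must contain both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  n <- length(s)
  nneg <- sum(l == 0)
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  ## correct[j + 1] = number classified correctly when the top-j scores are
  ## called positive; j = 0 means everything negative.
  correct <- c(nneg, tp + (nneg - fp))
  realizable <- c(TRUE, s > c(s[-1L], -Inf))  # can't cut inside a tied block
  acc <- correct / n
  acc[!realizable] <- -Inf
  j <- which.max(acc) - 1L
  threshold <- if (j == 0L) s[1L] + 1 else if (j == n) s[n] else (s[j] + s[j + 1L]) / 2
  list(threshold = threshold, accuracy = correct[j + 1L] / n)
}

#' Classification accuracy with a normal-approximation confidence interval
#'
#' `p = n_correct / n_total` with the Wald interval
#' `p +/- z_{1-alpha/2} sqrt(p (1 - p) / n_total)`, clipped to `[0, 1]`.
#'
#' @param n_correct,n_total Correct and total classification counts.
#' @param alpha Significance level (default 0.05, i.e. 95% intervals).
#' @return Named numeric vector `accuracy`, `ci_low`, `ci_high`.
#' @export
accuracy_ci <- function(n_correct, n_total, alpha = 0.05) {
  if (n_total < 1L || n_correct < 0L || n_correct > n_total) {
    stop("need 0 <= n_correct <= n_total with n_total >= 1")
  }
  p <- n_correct / n_total
  half <- qnorm(1 - alpha / 2) * sqrt(p * (1 - p) / n_total)
  c(accuracy = p, ci_low = max(0, p - half), ci_high = min(1, p + half))
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability that a positive sequence outscores a negative one,
#' estimated as the fraction of (positive, negative) pairs won, ties counted
#' one half. Computed via midranks, equivalent to pair enumeration.
#'
#' @param scores_pos,scores_neg Non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("both score vectors must be non-empty")
  }
  np <- length(scores_pos)
  nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Mann-Whitney confidence interval for an AUC
#'
#' Normal-approximation interval using the Hanley-McNeil variance of the
#' Mann-Whitney statistic, clipped to `[0, 1]`.
#'
#' @param auc_value Point estimate of the AUC.
#' @param n_pos,n_neg Numbers of positive and negative sequences (>= 1).
#' @param alpha Significance level (default 0.05).
#' @return Named numeric vector `ci_low`, `ci_high`.
#' @export
auc_ci_mann_whitney <- function(auc_value, n_pos, n_neg, alpha = 0.05) {
  if (n_pos < 1L || n_neg < 1L) stop("`n_pos` and `n_neg` must be >= 1")
  a <- auc_value
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  v <- (a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
    (n_pos * n_neg)
  v <- max(v, 0)
  half <- qnorm(1 - alpha / 2) * sqrt(v)
  c(ci_low = max(0, a - half), ci_high = min(1, a + half))
}

#' Construct an evaluation result
#'
#' @param metric `"accuracy"` or `"auc"`.
#' @param value Point estimate in `[0, 1]`.
#' @param ci_low,ci_high Confidence bounds.
#' @param n_pos,n_neg Class sizes.
#' @param threshold Classification threshold, or `NA` for AUC results.
#' @return An `eval_result`.
#' @export
eval_result <- function(metric, value, ci_low, ci_high, n_pos, n_neg,
                        threshold = NA_real_) {
  metric <- match.arg(metric, c("accuracy", "auc"))
  stopifnot(ci_low <= value + 1e-12, value <= ci_high + 1e-12)
  structure(list(metric = metric, value = value, ci_low = ci_low,
                 ci_high = ci_high, n_pos = n_pos, n_neg = n_neg,
                 threshold = threshold),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s = %.4f  [95%% CI %.4f, %.4f]  (n_pos = %d, n_neg = %d%s)\n",
              x$metric, x$value, x$ci_low, x$ci_high, x$n_pos, x$n_neg,
              if (is.na(x$threshold)) "" else sprintf(", threshold = %.4g", x$threshold)))
  invisible(x)
}

#' @export
as.data.frame.eval_result <- function(x, ...) {
  data.frame(metric = x$metric, value = x$value, ci_low = x$ci_low,
             ci_high = x$ci_high, n_pos = x$n_pos, n_neg = x$n_neg,
             threshold = x$threshold)
}

## Extract the central window of each sequence (midpoint-centered, or around
## a supplied 1-based summit position, clamped to stay inside the sequence).
center_windows <- function(seqs, width, summits = NULL) {
  lens <- nchar(seqs)
  keep <- lens >= width
  if (!all(keep)) {
    warning(sum(!keep), " sequence(s) shorter than the ", width,
            " nt center window were skipped")
  }
  seqs <- seqs[keep]
  lens <- lens[keep]
  if (is.null(summits)) {
    start <- floor((lens - width) / 2) + 1L
  } else {
    summits <- summits[keep]
    start <- pmin(pmax(summits - floor(width / 2), 1L), lens - width + 1L)
  }
  substring(seqs, start, start + width - 1L)
}

#' Evaluate a k-mer model on peak sequences by AUC
#'
#' Scores positive (true peak) and negative sequences with
#' [score_sequences()] — either the full regions or fixed-width windows
#' around each peak center — and reports the Mann-Whitney AUC with its
#' confidence interval. Sequences shorter than the center window are skipped
#' with a warning.
#'
#' @param model A `kmer_model`.
#' @param positive_seqs,negative_seqs Character vectors of peak sequences.
#' @param region_mode `"full"` (whole region) or `"center"`.
#' @param center_width Width of the central window in nt (commonly 50 or 100).
#' @param pos_summits,neg_summits Optional 1-based summit positions overriding
#'   midpoint centering.
#' @param alpha Significance level for the CI.
#' @return An `eval_result` with `metric = "auc"`.
#' @export
evaluate_chipseq <- function(model, positive_seqs, negative_seqs,
                             region_mode = c("full", "center"),
                             center_width = 100, pos_summits = NULL,
                             neg_summits = NULL, alpha = 0.05) {
  region_mode <- match.arg(region_mode)
  if (!length(positive_seqs) || !length(negative_seqs)) {
    stop("both sequence sets must be non-empty")
  }
  positive_seqs <- normalize_seqs(positive_seqs)
  negative_seqs <- normalize_seqs(negative_seqs)
  if (region_mode == "center") {
    positive_seqs <- center_windows(positive_seqs, center_width, pos_summits)
    negative_seqs <- center_windows(negative_seqs, center_width, neg_summits)
    if (!length(positive_seqs) || !length(negative_seqs)) {
      stop("no sequences remain after center-window extraction")
    }
  }
  sp <- score_sequences(model, positive_seqs)
  sn <- score_sequences(model, negative_seqs)
  a <- auc(sp, sn)
  ci <- auc_ci_mann_whitney(a, length(sp), length(sn), alpha = alpha)
  eval_result("auc", a, ci[["ci_low"]], ci[["ci_high"]],
              n_pos = length(sp), n_neg = length(sn))
}

#' Train and evaluate a k-mer classifier on SELEX reads
#'
#' The full pipeline of a single experiment: split the enriched reads 7:3
#' into training and test sets, pair each with an equal number of uniform
#' random negatives (or a supplied unbound set, split the same way), build
#' the k-mer table from the training data, select features, fit affinities,
#' pick the optimal threshold on training scores, and report training and
#' test accuracy with normal-approximation confidence intervals.
#'
#' @param bound Enriched (bound) reads.
#' @param unbound Optional unbound reads; when `NULL`, uniform random reads
#'   matched in number and length are generated.
#' @param spec A [kmer_spec()].
#' @param kmers Optional explicit feature list, bypassing selection.
#' @param n_kmers Number of k-mers to select (when `kmers` is `NULL`).
#' @param criterion Selection criterion for [select_top()].
#' @param ridge_lambda Ridge penalty for [fit_affinities()].
#' @param train_fraction Training fraction (default 0.7).
#' @param seed Optional seed governing the split and negative generation.
#' @return List with `model`, `kmers`, `threshold`, `train` and `test`
#'   (`eval_result`s), and the underlying `splits`.
#' @export
selex_train_test <- function(bound, unbound = NULL, spec = kmer_spec(),
                             kmers = NULL, n_kmers = 100,
                             criterion = "frequency", ridge_lambda = 1e-6,
                             train_fraction = 0.7, seed = NULL) {
  bound <- normalize_seqs(bound)
  with_seed(seed, {
    sp <- split_reads(bound, train_fraction)
    if (is.null(unbound)) {
      len <- nchar(bound[1L])
      neg_train <- generate_random_reads(length(sp$train), len)
      neg_test <- generate_random_reads(length(sp$test), len)
    } else {
      spn <- split_reads(normalize_seqs(unbound), train_fraction)
      neg_train <- spn$train
      neg_test <- spn$test
    }
    if (is.null(kmers)) {
      tab <- build_kmer_table(sp$train, neg_train, spec)
      kmers <- select_top(tab, criterion = criterion, n = n_kmers)
    }
    reads_tr <- c(sp$train, neg_train)
    b_tr <- rep(c(1, 0), c(length(sp$train), length(neg_train)))
    A <- build_design_matrix(reads_tr, kmers, spec)
    model <- fit_affinities(A, b_tr, ridge_lambda = ridge_lambda, spec = spec)
    s_tr <- as.numeric(A %*% model$affinities)
    th <- optimal_threshold(s_tr, b_tr)
    tr_ci <- accuracy_ci(round(th$accuracy * length(b_tr)), length(b_tr))
    train_eval <- eval_result("accuracy", tr_ci[["accuracy"]], tr_ci[["ci_low"]],
                              tr_ci[["ci_high"]], n_pos = length(sp$train),
                              n_neg = length(neg_train), threshold = th$threshold)
    s_te <- score_sequences(model, c(sp$test, neg_test))
    b_te <- rep(c(1, 0), c(length(sp$test), length(neg_test)))
    n_correct <- sum((s_te >= th$threshold) == (b_te == 1))
    te_ci <- accuracy_ci(n_correct, length(b_te))
    test_eval <- eval_result("accuracy", te_ci[["accuracy"]], te_ci[["ci_low"]],
                             te_ci[["ci_high"]], n_pos = length(sp$test),
                             n_neg = length(neg_test), threshold = th$threshold)
    list(model = model, kmers = kmers, threshold = th$threshold,
         train = train_eval, test = test_eval,
         splits = list(train_pos = sp$train, test_pos = sp$test,
                       train_neg = neg_train, test_neg = neg_test))
  })
}
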