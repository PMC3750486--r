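## The three k-mer feature-selection strategies: most frequent, most enriched
## (count difference or fold change), and greedy backward elimination guided
## by 10-fold cross-validation within the training data.

#' Select the top-n k-mers from a k-mer table
#'
#' Ranks the table by the chosen criterion and returns the best `n` k-mers:
#' `frequency` = `count_bound + count_unbound` (the most common words in the
#' whole data), `difference` = `count_bound - count_unbound`, and
#' `fold_change` = `(count_bound + c) / (count_unbound + c)` with pseudocount
#' `c` so k-mers absent from the unbound set stay finite. Ties are broken
#' deterministically by (k, lexicographic).
#'
#' @param table A `kmer_table` from [build_kmer_table()].
#' @param criterion `"frequency"`, `"difference"` or `"fold_change"`.
#' @param n Number of k-mers to return (>= 1). If larger than the table, all
#'   k-mers are returned with a warning.
#' @param pseudocount Pseudocount for `fold_change` (default 1).
#' @return Ordered character vector of selected k-mers (best first).
#' @export
select_top <- function(table, criterion = c("frequency", "difference", "fold_change"),
                       n, pseudocount = 1) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(table, "kmer_table"))
  if (!is.numeric(n) || length(n) != 1L || n < 1L) stop("`n` must be a positive integer")
  df <- as.data.frame(table)
  stat <- switch(criterion,
    frequency = df$count_bound + df$count_unbound,
    difference = df$count_bound - df$count_unbound,
    fold_change = (df$count_bound + pseudocount) / (df$count_unbound + pseudocount)
  )
  if (n > nrow(df)) {
    warning("requested ", n, " k-mers but the table has only ", nrow(df),
            "; returning all")
    n <- nrow(df)
  }
  ord <- order(-stat, df$k, df$kmer)
  df$kmer[ord][seq_len(n)]
}

## Stratified fold labels: each class permuted and dealt round-robin.
stratified_folds <- function(labels, folds) {
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      stop("each class needs at least `folds` members for stratified CV")
    }
    id[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

## CV accuracy of the model restricted to `cols`, on one fold: refit on the
## fold's training part via the precomputed Gram system, threshold on the
## training part, evaluate on the fold's validation part.
cv_fold_accuracy <- function(fd, cols, ridge_lambda) {
  m <- length(cols)
  x <- solve(fd$G[cols, cols, drop = FALSE] + diag(ridge_lambda, m), fd$c[cols])
  s_tr <- as.numeric(fd$A_tr[, cols, drop = FALSE] %*% x)
  th <- optimal_threshold(s_tr, fd$b_tr)$threshold
  s_va <- as.numeric(fd$A_va[, cols, drop = FALSE] %*% x)
  mean((s_va >= th) == (fd$b_va == 1))
}

#' Greedy backward elimination of k-mers by cross-validated accuracy
#'
#' Wrapper feature selection: starting from `start_kmers`, repeatedly remove
#' the k-mer whose removal improves the mean k-fold cross-validation
#' classification accuracy most (or hurts it least), down to `min_size`
#' features. Folds are stratified by label and fixed by `seed`; within each
#' fold the model is refit on the fold's training part, the classification
#' threshold is re-optimized on that same part, and accuracy is measured on
#' the fold's held-out part. The external test set never enters this
#' procedure, which is what guards the final performance estimate against
#' selection bias. Ties between removal candidates are broken by removing the
#' lexicographically last k-mer, making the trajectory reproducible.
#'
#' @param bound,unbound Training reads of each class (each with at least
#'   `folds` members).
#' @param start_kmers Starting feature set (its order is preserved).
#' @param folds Number of CV folds (default 10).
#' @param min_size Smallest feature-set size to reach (>= 1).
#' @param spec A [kmer_spec()].
#' @param ridge_lambda Ridge penalty used in every refit.
#' @param seed Optional seed fixing the fold partition.
#' @return A `selection_trajectory`: a data.frame with columns `step`,
#'   `removed_kmer`, `remaining_size`, `cv_accuracy`, plus attributes
#'   `start_kmers` and `final_kmers`.
#' @export
cv_backward_eliminate <- function(bound, unbound, start_kmers, folds = 10,
                                  min_size = 1, spec = kmer_spec(),
                                  ridge_lambda = 1e-6, seed = NULL) {
  if (!length(start_kmers)) stop("`start_kmers` must be non-empty")
  if (folds < 2L) stop("`folds` must be >= 2")
  if (min_size < 1L) stop("`min_size` must be >= 1")
  if (length(start_kmers) < min_size) {
    stop("`start_kmers` (", length(start_kmers), ") is smaller than `min_size` (",
         min_size, ")")
  }
  bound <- normalize_seqs(bound)
  unbound <- normalize_seqs(unbound)
  reads <- c(bound, unbound)
  b <- rep(c(1, 0), c(length(bound), length(unbound)))
  A <- build_design_matrix(reads, start_kmers, spec)
  fold_id <- with_seed(seed, stratified_folds(b, folds))
  fold_data <- lapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    A_tr <- A[tr, , drop = FALSE]
    list(G = as.matrix(Matrix::crossprod(A_tr)),
         c = as.numeric(Matrix::crossprod(A_tr, b[tr])),
         A_tr = A_tr, b_tr = b[tr],
         A_va = A[!tr, , drop = FALSE], b_va = b[!tr])
  })

  cur <- seq_along(start_kmers)
  n_steps <- length(start_kmers) - min_size
  removed <- character(n_steps)
  remaining <- integer(n_steps)
  cv_acc <- numeric(n_steps)
  step <- 0L
  while (length(cur) > min_size) {
    accs <- vapply(cur, function(drop_j) {
      cols <- cur[cur != drop_j]
      mean(vapply(fold_data, cv_fold_accuracy, 0, cols = cols,
                  ridge_lambda = ridge_lambda))
    }, numeric(1))
    best <- max(accs)
    tied <- cur[accs >= best - 1e-12]
    drop_idx <- tied[order(start_kmers[tied])][length(tied)]
    cur <- cur[cur != drop_idx]
    step <- step + 1L
    removed[step] <- start_kmers[drop_idx]
    remaining[step] <- length(cur)
    cv_acc[step] <- best
  }
  traj <- data.frame(step = seq_len(n_steps), removed_kmer = removed,
                     remaining_size = remaining, cv_accuracy = cv_acc,
                     stringsAsFactors = FALSE)
  attr(traj, "start_kmers") <- start_kmers
  attr(traj, "final_kmers") <- start_kmers[cur]
  attr(traj, "folds") <- folds
  attr(traj, "seed") <- seed
  class(traj) <- c("selection_trajectory", "data.frame")
  traj
}

#' Feature set at a given size along a selection trajectory
#'
#' Reconstructs the k-mer set that remained when the trajectory had been
#' reduced to `size` features.
#'
#' @param trajectory A `selection_trajectory`.
#' @param size Target set size; must lie between the final size and the start
#'   size.
#' @return Character vector of k-mers, in start-set order.
#' @export
kmers_at_size <- function(trajectory, size) {
  stopifnot(inherits(trajectory, "selection_trajectory"))
  start <- attr(trajectory, "start_kmers")
  if (size > length(start) || size < min(c(trajectory$remaining_size, length(start)))) {
    stop("`size` outside the trajectory range")
  }
  n_remove <- length(start) - size
  setdiff(start, trajectory$removed_kmer[seq_len(n_remove)])
}

#' @export
print.selection_trajectory <- function(x, ...) {
  start <- attr(x, "start_kmers")
  cat("CV backward-elimination trajectory: ", length(start), " -> ",
      length(attr(x, "final_kmers")), " k-mers over ", nrow(x), " steps (",
      attr(x, "folds"), "-fold CV)\n", sep = "")
  if (nrow(x)) {
    best <- x[which.max(x$cv_accuracy), ]
    cat(sprintf("  best CV accuracy %.4f at %d k-mers\n",
                best$cv_accuracy, best$remaining_size))
  }
  invisible(x)
}
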