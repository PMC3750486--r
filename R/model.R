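## The linear k-mer model: binary presence design matrix A, least-squares
## solution of A x = b for the per-k-mer affinities x, and scoring of
## arbitrary sequences as the sum of affinities of the k-mers they contain.

#' Build the binary presence design matrix
#'
#' Rows are reads (in input order), columns are k-mers (in the given order);
#' entry `A[i, j]` is 1 if the j-th k-mer occurs in the i-th read (on either
#' strand when `spec$both_strands`), 0 otherwise. The result is a sparse
#' `dgCMatrix`, since most entries are zero.
#'
#' @param reads Character vector of reads.
#' @param kmers Character vector of unique feature k-mers; must already be
#'   canonical when `spec$canonicalize` is set.
#' @param spec A [kmer_spec()]; only the strand flags are used here (the k of
#'   each column is its own length).
#' @return A sparse binary matrix with `colnames` equal to `kmers`.
#' @export
build_design_matrix <- function(reads, kmers, spec = kmer_spec()) {
  reads <- normalize_seqs(reads)
  n <- length(reads)
  m <- length(kmers)
  if (m == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, 0L), dimnames = list(NULL, character(0))))
  }
  kmers <- normalize_seqs(kmers, what = "k-mer", allow_n = FALSE)
  if (anyDuplicated(kmers)) {
    stop("duplicate k-mer columns: ", paste(unique(kmers[duplicated(kmers)]), collapse = ", "))
  }
  if (spec$canonicalize && !identical(kmers, canonical_kmer(kmers))) {
    stop("k-mers must be canonical when `spec$canonicalize` is TRUE; see canonical_kmer()")
  }
  rcs <- reverse_complement(kmers)
  hits <- vector("list", m)
  for (j in seq_len(m)) {
    h <- grepl(kmers[j], reads, fixed = TRUE)
    if (spec$both_strands && rcs[j] != kmers[j]) {
      h <- h | grepl(rcs[j], reads, fixed = TRUE)
    }
    hits[[j]] <- which(h)
  }
  Matrix::sparseMatrix(i = unlist(hits, use.names = FALSE),
                       j = rep.int(seq_len(m), lengths(hits)),
                       x = 1,
                       dims = c(n, m),
                       dimnames = list(NULL, kmers))
}

new_kmer_model <- function(kmers, affinities, ridge_lambda, spec, meta) {
  structure(list(kmers = kmers,
                 affinities = setNames(as.numeric(affinities), kmers),
                 ridge_lambda = ridge_lambda,
                 spec = spec,
                 meta = meta),
            class = "kmer_model")
}

#' Construct a k-mer model from a named affinity vector
#'
#' Convenience constructor for hand-specified or simulated affinity maps.
#' Names are the k-mers; they are canonicalized when the spec requires it.
#'
#' @param affinities Named numeric vector, names being k-mers.
#' @param spec A [kmer_spec()]; defaults to one covering the observed word
#'   lengths with canonical both-strand features.
#' @param ridge_lambda Recorded ridge penalty (not used by scoring).
#' @return A `kmer_model`.
#' @export
kmer_model <- function(affinities, spec = NULL, ridge_lambda = NA_real_) {
  if (!is.numeric(affinities) ||
      (length(affinities) > 0 &&
       (is.null(names(affinities)) || any(!nzchar(names(affinities)))))) {
    stop("`affinities` must be a named numeric vector of k-mer affinities")
  }
  if (length(affinities) == 0L) names(affinities) <- character(0)
  kmers <- normalize_seqs(names(affinities), what = "k-mer", allow_n = FALSE)
  if (is.null(spec)) {
    spec <- if (length(kmers)) kmer_spec(k = sort(unique(nchar(kmers)))) else kmer_spec()
  }
  if (spec$canonicalize) {
    kmers <- canonical_kmer(kmers)
    if (anyDuplicated(kmers)) {
      stop("k-mers collide after canonicalization: ",
           paste(unique(kmers[duplicated(kmers)]), collapse = ", "))
    }
  }
  new_kmer_model(kmers, unname(affinities), ridge_lambda, spec,
                 meta = list(n_reads = NA_integer_, residual_norm = NA_real_))
}

#' Fit k-mer affinities by (ridge-regularized) least squares
#'
#' Solves `min_x ||A x - b||^2 + lambda ||x||^2` for the affinity vector `x`.
#' `b` is the binary label vector (1 = enriched/bound read, 0 = random read).
#' The small default ridge penalty exists purely for numerical conditioning:
#' presence columns of co-occurring k-mers are often exactly collinear, and
#' with `ridge_lambda > 0` the normal equations are always solvable. With
#' `ridge_lambda = 0` a rank-deficient design is an error.
#'
#' @param A Design matrix from [build_design_matrix()] (dense or sparse),
#'   with column names.
#' @param b Binary label vector aligned to rows of `A`; both classes must be
#'   present.
#' @param ridge_lambda Non-negative ridge penalty (default `1e-6`).
#' @param spec The [kmer_spec()] the columns were built under; stored in the
#'   model so that scoring reproduces training presence semantics.
#' @return A `kmer_model` with fields `kmers`, `affinities`, `ridge_lambda`,
#'   `spec` and `meta` (`n_reads`, `residual_norm`).
#' @export
fit_affinities <- function(A, b, ridge_lambda = 1e-6, spec = kmer_spec()) {
  b <- as.numeric(b)
  if (nrow(A) != length(b)) stop("rows of `A` must match length of `b`")
  if (length(unique(b)) < 2L) stop("label vector `b` must contain both classes")
  if (!is.numeric(ridge_lambda) || length(ridge_lambda) != 1L || ridge_lambda < 0) {
    stop("`ridge_lambda` must be a single non-negative number")
  }
  n <- nrow(A)
  m <- ncol(A)
  if (is.null(colnames(A)) && m > 0L) stop("`A` must carry k-mer column names")
  if (ridge_lambda == 0) {
    Ad <- as.matrix(A)
    qrA <- qr(Ad)
    if (qrA$rank < m) {
      stop("design matrix is rank deficient (rank ", qrA$rank, " < ", m,
           " columns); set ridge_lambda > 0")
    }
    x <- qr.coef(qrA, b)
  } else {
    if (m > n) {
      warning("underdetermined system (", m, " k-mers > ", n,
              " reads); returning the ridge minimum-norm solution")
    }
    G <- as.matrix(Matrix::crossprod(A)) + diag(ridge_lambda, m)
    x <- solve(G, as.numeric(Matrix::crossprod(A, b)))
  }
  x <- as.numeric(x)
  resid <- sqrt(sum((as.numeric(A %*% x) - b)^2))
  new_kmer_model(colnames(A), x, ridge_lambda, spec,
                 meta = list(n_reads = n, residual_norm = resid))
}

## Per-k-mer occurrence counts (both strands), for occurrence-weighted scoring.
occurrence_matrix <- function(reads, kmers, spec) {
  dss <- Biostrings::DNAStringSet(reads)
  rcs <- reverse_complement(kmers)
  cols <- lapply(seq_along(kmers), function(j) {
    cnt <- Biostrings::vcountPattern(kmers[j], dss)
    if (spec$both_strands && rcs[j] != kmers[j]) {
      cnt <- cnt + Biostrings::vcountPattern(rcs[j], dss)
    }
    cnt
  })
  out <- do.call(cbind, cols)
  colnames(out) <- kmers
  out
}

#' Score sequences with a k-mer model
#'
#' The predicted binding affinity of a sequence is the sum of the affinities
#' of the model k-mers present in it — the same binary presence rule used to
#' build the design matrix, so for a training read the score equals the
#' corresponding entry of `A %*% x` exactly. Set `occurrence = TRUE` to weight
#' each k-mer by its occurrence count instead (exploratory; not the training
#' semantics).
#'
#' @param model A `kmer_model`.
#' @param seqs Character vector of sequences (any lengths).
#' @param occurrence Use occurrence counts instead of binary presence.
#' @return Numeric vector of scores.
#' @export
score_sequences <- function(model, seqs, occurrence = FALSE) {
  stopifnot(inherits(model, "kmer_model"))
  seqs <- normalize_seqs(seqs)
  if (length(model$kmers) == 0L) return(rep(0, length(seqs)))
  D <- if (occurrence) occurrence_matrix(seqs, model$kmers, model$spec)
  else build_design_matrix(seqs, model$kmers, model$spec)
  as.numeric(D %*% model$affinities)
}

#' @rdname score_sequences
#' @param s A single sequence.
#' @export
score_sequence <- function(model, s, occurrence = FALSE) {
  if (length(s) != 1L) stop("`s` must be a single sequence")
  score_sequences(model, s, occurrence = occurrence)
}

#' @export
print.kmer_model <- function(x, ...) {
  cat("linear k-mer model: ", length(x$kmers), " k-mers (k in {",
      paste(x$spec$k, collapse = ", "), "}), ridge_lambda = ",
      format(x$ridge_lambda), "\n", sep = "")
  if (!is.na(x$meta$n_reads)) {
    cat("  trained on ", x$meta$n_reads, " reads, residual norm ",
        format(x$meta$residual_norm, digits = 4), "\n", sep = "")
  }
  if (length(x$affinities)) {
    top <- sort(x$affinities, decreasing = TRUE)
    top <- head(top, 5L)
    cat("  top affinities: ",
        paste(sprintf("%s=%.3g", names(top), top), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
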