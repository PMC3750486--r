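## Position weight matrices: ingestion from MEME minimal / JASPAR-style /
## plain matrix files, log-odds max-score scanning, PWM-based classification
## for head-to-head comparisons with the k-mer model, and alignment of top
## k-mers against a motif for reporting.

#' Construct a PWM from base probabilities
#'
#' Low-level constructor. Rows are motif positions, columns the bases
#' A, C, G, T; every row must sum to 1 and all entries must be strictly
#' positive (apply a pseudocount upstream if needed).
#'
#' @param probs L x 4 numeric matrix of base probabilities.
#' @param background Background base frequencies (default uniform 0.25).
#' @param pseudocount Pseudocount that was applied, recorded for reference.
#' @return An object of class `pwm`.
#' @export
pwm <- function(probs, background = rep(0.25, 4), pseudocount = NA_real_) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("a PWM must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1L) stop("a PWM must have at least one position")
  if (!is.numeric(probs) || anyNA(probs)) stop("PWM entries must be numeric")
  if (any(probs <= 0)) stop("PWM probabilities must be strictly positive; apply a pseudocount")
  if (any(abs(rowSums(probs) - 1) > 1e-9)) stop("each PWM row must sum to 1")
  if (length(background) != 4L || any(background <= 0)) {
    stop("`background` must be 4 positive frequencies")
  }
  dimnames(probs) <- list(NULL, DNA_BASES)
  structure(list(probs = probs, background = background / sum(background),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' Build a PWM from a count matrix
#'
#' Adds `pseudocount` to every count and normalizes each row, so a
#' 1-position count row (10, 0, 0, 0) with pseudocount 1 becomes
#' (11/14, 1/14, 1/14, 1/14).
#'
#' @param counts L x 4 non-negative count matrix.
#' @param pseudocount Added to every cell before normalization (default 1).
#' @inheritParams pwm
#' @return A `pwm`.
#' @export
pwm_from_counts <- function(counts, pseudocount = 1, background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop("`counts` must have 4 columns (A, C, G, T)")
  if (any(counts < 0)) stop("`counts` must be non-negative")
  p <- counts + pseudocount
  pwm(p / rowSums(p), background = background, pseudocount = pseudocount)
}

#' Build a PWM from a frequency matrix
#'
#' When `pseudocount` is `NULL`, a pseudocount of 0.01 is applied only if
#' some entry is zero; already-positive frequency matrices round-trip
#' unchanged.
#'
#' @param freqs L x 4 frequency matrix (rows roughly summing to 1).
#' @param pseudocount Added to every cell before renormalization, or `NULL`
#'   for the conditional default.
#' @inheritParams pwm
#' @return A `pwm`.
#' @export
pwm_from_freqs <- function(freqs, pseudocount = NULL, background = rep(0.25, 4)) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != 4L) stop("`freqs` must have 4 columns (A, C, G, T)")
  if (is.null(pseudocount)) pseudocount <- if (any(freqs <= 0)) 0.01 else 0
  p <- freqs + pseudocount
  pwm(p / rowSums(p), background = background, pseudocount = pseudocount)
}

#' Build a naive count PWM from aligned motif instances
#'
#' Stacks equal-length instance strings (already aligned, e.g. planted motif
#' variants whose alignment is known by construction), counts bases per
#' position with optional weights, and applies [pwm_from_counts()]. This is
#' the simulator's benchmark PWM; it deliberately assumes positional
#' independence.
#'
#' @param instances Character vector of equal-length motif instances.
#' @param weights Optional non-negative instance weights (default 1 each).
#' @inheritParams pwm_from_counts
#' @return A `pwm`.
#' @export
pwm_from_instances <- function(instances, weights = NULL, pseudocount = 1,
                               background = rep(0.25, 4)) {
  instances <- normalize_seqs(instances, what = "motif instance", allow_n = FALSE)
  L <- unique(nchar(instances))
  if (length(L) != 1L) stop("all instances must have equal length")
  if (is.null(weights)) weights <- rep(1, length(instances))
  if (length(weights) != length(instances) || any(weights < 0)) {
    stop("`weights` must be non-negative, one per instance")
  }
  counts <- matrix(0, L, 4L, dimnames = list(NULL, DNA_BASES))
  chars <- matrix(match(unlist(strsplit(instances, "", fixed = TRUE)), DNA_BASES),
                  nrow = length(instances), byrow = TRUE)
  for (pos in seq_len(L)) {
    for (bidx in 1:4) counts[pos, bidx] <- sum(weights[chars[, pos] == bidx])
  }
  pwm_from_counts(counts, pseudocount = pseudocount, background = background)
}

#' Consensus sequence of a PWM
#'
#' @param x A `pwm`.
#' @return The highest-probability base at each position, as one string.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$probs, 1L, which.max)], collapse = "")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM of length ", nrow(x$probs), ", consensus ", pwm_consensus(x), "\n", sep = "")
  print(round(x$probs, 3))
  invisible(x)
}

#' Read a PWM from a file
#'
#' Supports MEME minimal format (`letter-probability matrix:` block),
#' JASPAR-style count matrices (`A [ 1 2 3 ]` rows, optional `>` header) and
#' plain whitespace-separated L x 4 matrices (a 4 x L matrix is transposed).
#' Counts get a pseudocount of 1; frequency matrices get 0.01 only when they
#' contain zeros. A matrix whose entries are all at most 1 with rows summing
#' to about 1 is treated as frequencies, otherwise as counts.
#'
#' @param path Path to the motif file.
#' @param format `"auto"` (default), `"meme"`, `"jaspar"` or `"matrix"`.
#' @param pseudocount Override the format-specific default pseudocount.
#' @inheritParams pwm
#' @return A `pwm`.
#' @export
read_pwm <- function(path, format = c("auto", "meme", "jaspar", "matrix"),
                     pseudocount = NULL, background = rep(0.25, 4)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "auto") {
    format <- if (any(grepl("letter-probability matrix", lines, fixed = TRUE)) ||
                  any(grepl("^MEME version", lines))) "meme"
    else if (any(grepl("^[ACGT]\\s*[\\[|]", lines))) "jaspar"
    else "matrix"
  }
  switch(format,
    meme = read_pwm_meme(lines, pseudocount, background),
    jaspar = read_pwm_jaspar(lines, pseudocount, background),
    matrix = read_pwm_matrix(lines, pseudocount, background)
  )
}

parse_numbers <- function(line) {
  m <- regmatches(line, gregexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", line))[[1]]
  as.numeric(m)
}

read_pwm_meme <- function(lines, pseudocount, background) {
  hdr <- grep("letter-probability matrix", lines, fixed = TRUE)
  if (!length(hdr)) stop("not a MEME minimal motif file: no letter-probability matrix block")
  i <- hdr[1L] + 1L
  rows <- list()
  while (i <= length(lines)) {
    nums <- parse_numbers(lines[i])
    if (length(nums) == 0L) break
    if (length(nums) != 4L) {
      stop("malformed MEME probability row at line ", i, ": expected 4 values, got ",
           length(nums))
    }
    rows[[length(rows) + 1L]] <- nums
    i <- i + 1L
  }
  if (!length(rows)) stop("empty letter-probability matrix block")
  pwm_from_freqs(do.call(rbind, rows), pseudocount = pseudocount,
                 background = background)
}

read_pwm_jaspar <- function(lines, pseudocount, background) {
  rows <- grep("^[ACGT]\\b|^[ACGT]\\s*[\\[|]", lines)
  if (length(rows) != 4L) {
    stop("JASPAR-style matrix needs exactly 4 base rows (A, C, G, T); found ",
         length(rows))
  }
  bases <- substr(lines[rows], 1L, 1L)
  if (!setequal(bases, DNA_BASES)) stop("JASPAR rows must cover A, C, G and T")
  vals <- lapply(lines[rows], function(l) parse_numbers(sub("^[ACGT]", "", l)))
  lens <- lengths(vals)
  if (length(unique(lens)) != 1L || lens[1L] == 0L) {
    stop("JASPAR rows have unequal lengths at line(s) ",
         paste(rows[lens != max(lens)], collapse = ", "))
  }
  counts <- matrix(0, nrow = lens[1L], ncol = 4L, dimnames = list(NULL, DNA_BASES))
  for (r in seq_len(4L)) counts[, bases[r]] <- vals[[r]]
  interpret_matrix(counts, pseudocount, background)
}

read_pwm_matrix <- function(lines, pseudocount, background) {
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file")
  rows <- lapply(seq_along(lines), function(i) {
    nums <- parse_numbers(lines[i])
    if (!length(nums)) stop("non-numeric matrix row at line ", i)
    nums
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) stop("ragged matrix rows (unequal column counts)")
  m <- do.call(rbind, rows)
  if (ncol(m) != 4L && nrow(m) == 4L) m <- t(m)
  if (ncol(m) != 4L) stop("matrix must be L x 4 or 4 x L; got ", nrow(m), " x ", ncol(m))
  interpret_matrix(m, pseudocount, background)
}

## Frequencies if everything <= 1 and rows sum to ~1, otherwise counts.
interpret_matrix <- function(m, pseudocount, background) {
  looks_freq <- all(m <= 1 + 1e-9) && all(abs(rowSums(m) - 1) < 1e-6)
  if (looks_freq) {
    pwm_from_freqs(m, pseudocount = pseudocount, background = background)
  } else {
    pwm_from_counts(m, pseudocount = if (is.null(pseudocount)) 1 else pseudocount,
                    background = background)
  }
}

#' Write a PWM to a file
#'
#' `"matrix"` writes the probabilities as a plain L x 4 matrix at full double
#' precision (round-trips through [read_pwm()] to within 1e-12); `"meme"`
#' writes a MEME minimal motif.
#'
#' @param x A `pwm`.
#' @param path Output path.
#' @param format `"matrix"` or `"meme"`.
#' @param name Motif name for MEME output.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path, format = c("matrix", "meme"), name = "motif") {
  format <- match.arg(format)
  stopifnot(inherits(x, "pwm"))
  rows <- apply(x$probs, 1L, function(r) paste(format_full(r), collapse = " "))
  if (format == "matrix") {
    writeLines(c("# PWM probabilities, columns A C G T", rows), path)
  } else {
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 paste("MOTIF", name),
                 sprintf("letter-probability matrix: alength= 4 w= %d", nrow(x$probs)),
                 rows), path)
  }
  invisible(path)
}

## Vectorized max log-odds scan. Returns NA for reads shorter than the motif
## or whose every window contains N.
pwm_max_scores <- function(x, reads, both_strands = TRUE) {
  stopifnot(inherits(x, "pwm"))
  reads <- normalize_seqs(reads)
  L <- nrow(x$probs)
  lod <- log(x$probs) - matrix(log(x$background), L, 4L, byrow = TRUE)
  fwd <- scan_one_strand(lod, reads, L)
  if (!both_strands) return(fwd)
  rev <- scan_one_strand(lod, reverse_complement(reads), L)
  pmax(fwd, rev, na.rm = TRUE)
}

scan_one_strand <- function(lod, reads, L) {
  n <- length(reads)
  out <- rep(NA_real_, n)
  lens <- nchar(reads)
  for (len in unique(lens)) {
    if (len < L) next
    ii <- which(lens == len)
    M <- matrix(match(unlist(strsplit(reads[ii], "", fixed = TRUE)), DNA_BASES),
                nrow = length(ii), byrow = TRUE)
    best <- rep(-Inf, length(ii))
    any_ok <- logical(length(ii))
    for (o in 0:(len - L)) {
      sc <- numeric(length(ii))
      for (j in seq_len(L)) sc <- sc + lod[j, ][M[, o + j]]
      ok <- !is.na(sc)
      upd <- ok & sc > best
      best[upd] <- sc[upd]
      any_ok <- any_ok | ok
    }
    out[ii] <- ifelse(any_ok, best, NA_real_)
  }
  out
}

#' Maximum log-odds score of a PWM over a sequence
#'
#' Scans every window of `s` (both strands by default) with the log-odds
#' matrix `log(probs / background)` and returns the maximum window score —
#' the score assigned to a read under PWM-based classification. Windows
#' containing `N` are excluded.
#'
#' @param x A `pwm`.
#' @param s A single sequence at least as long as the motif.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return Maximum window log-odds score; `NA` (with a warning) if every
#'   window contains `N`.
#' @export
scan_max_score <- function(x, s, both_strands = TRUE) {
  if (length(s) != 1L) stop("`s` must be a single sequence")
  s <- normalize_seqs(s)
  if (nchar(s) < nrow(x$probs)) {
    stop("sequence (", nchar(s), " nt) is shorter than the motif (",
         nrow(x$probs), " nt)")
  }
  out <- pwm_max_scores(x, s, both_strands = both_strands)
  if (is.na(out)) warning("every window contains N; score undefined")
  out
}

#' Classify reads with a PWM and report test accuracy
#'
#' The PWM benchmark path: every read is scored by its maximum log-odds
#' window score, the classification threshold is optimized on the training
#' scores, and accuracy with a normal-approximation CI is reported on the
#' test scores. Reads shorter than the motif are skipped with a warning.
#'
#' @param x A `pwm`.
#' @param train_pos,train_neg,test_pos,test_neg Read sets.
#' @param both_strands Scan both strands (default `TRUE`).
#' @return An `eval_result` with `metric = "accuracy"`.
#' @export
classify_with_pwm <- function(x, train_pos, train_neg, test_pos, test_neg,
                              both_strands = TRUE) {
  sc <- function(reads) pwm_max_scores(x, reads, both_strands = both_strands)
  s_tr <- c(sc(train_pos), sc(train_neg))
  b_tr <- rep(c(1, 0), c(length(train_pos), length(train_neg)))
  keep_tr <- !is.na(s_tr)
  s_te <- c(sc(test_pos), sc(test_neg))
  b_te <- rep(c(1, 0), c(length(test_pos), length(test_neg)))
  keep_te <- !is.na(s_te)
  n_skip <- sum(!keep_tr) + sum(!keep_te)
  if (n_skip > 0L) warning(n_skip, " read(s) shorter than the motif were skipped")
  th <- optimal_threshold(s_tr[keep_tr], b_tr[keep_tr])
  correct <- sum((s_te[keep_te] >= th$threshold) == (b_te[keep_te] == 1))
  ci <- accuracy_ci(correct, sum(keep_te))
  eval_result("accuracy", ci[["accuracy"]], ci[["ci_low"]], ci[["ci_high"]],
              n_pos = sum(keep_te & b_te == 1), n_neg = sum(keep_te & b_te == 0),
              threshold = th$threshold)
}

#' Align k-mers against a PWM
#'
#' For each k-mer, finds the strand and offset maximizing the summed log
#' probability of its bases under the PWM. The k-mer may overhang the motif;
#' overhanging positions are scored at the background. Both the k-mer and its
#' reverse complement are considered, so a k-mer and its reverse complement
#' receive identical best scores. Offsets are 0-based relative to the first
#' motif position; ties prefer the forward strand, then the smallest offset.
#'
#' @param x A `pwm`.
#' @param kmers Character vector of k-mers.
#' @return data.frame with columns `kmer`, `strand`, `offset`,
#'   `alignment_score`.
#' @export
align_kmers_to_pwm <- function(x, kmers) {
  stopifnot(inherits(x, "pwm"))
  if (!length(kmers)) {
    return(data.frame(kmer = character(0), strand = character(0),
                      offset = integer(0), alignment_score = numeric(0)))
  }
  kmers <- normalize_seqs(kmers, what = "k-mer", allow_n = FALSE)
  L <- nrow(x$probs)
  lp <- log(x$probs)
  lbg <- log(x$background)
  one <- function(w) {
    best <- NULL
    for (strand in c("+", "-")) {
      ww <- if (strand == "+") w else reverse_complement(w)
      bi <- match(strsplit(ww, "", fixed = TRUE)[[1]], DNA_BASES)
      kl <- length(bi)
      for (o in (-kl + 1L):(L - 1L)) {
        pos <- o + seq_len(kl)
        inside <- pos >= 1L & pos <= L
        s <- sum(lp[cbind(pos[inside], bi[inside])]) + sum(lbg[bi[!inside]])
        if (is.null(best) || s > best$alignment_score + 1e-12) {
          best <- list(strand = strand, offset = o, alignment_score = s)
        }
      }
    }
    data.frame(kmer = w, strand = best$strand, offset = best$offset,
               alignment_score = best$alignment_score)
  }
  do.call(rbind, lapply(kmers, one))
}
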