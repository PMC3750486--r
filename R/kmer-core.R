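## Sequence alphabet handling, reverse complement, canonical k-mers and the
## bound/unbound k-mer count table.

## Uppercase and validate a character vector of DNA sequences.
normalize_seqs <- function(x, what = "sequence", allow_n = TRUE) {
  if (!is.character(x)) stop("`", what, "` must be a character vector")
  x <- toupper(x)
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    stop("invalid ", what, ": characters outside the DNA alphabet in element(s) ",
         paste(head(which(bad), 5L), collapse = ", "))
  }
  x
}

#' Reverse complement of DNA sequences
#'
#' Vectorized Watson-Crick reverse complement over the alphabet
#' `{A, C, G, T, N}`; `N` maps to `N`. Input is case-normalized to uppercase.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement(c("ACGT", "AAAA"))
#' @export
reverse_complement <- function(x) {
  x <- normalize_seqs(x)
  out <- x
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
  }
  out
}

#' Canonical form of a k-mer
#'
#' Maps each k-mer to the lexicographically smaller of itself and its reverse
#' complement, so that one feature covers detection on both strands. `N` is
#' not allowed in k-mers.
#'
#' @param x Character vector of k-mers over `{A, C, G, T}`.
#' @return Character vector of canonical k-mers.
#' @examples
#' canonical_kmer(c("TTTT", "ACGT"))  # "AAAA", "ACGT"
#' @export
canonical_kmer <- function(x) {
  x <- normalize_seqs(x, what = "k-mer", allow_n = FALSE)
  rc <- reverse_complement(x)
  ifelse(x <= rc, x, rc)
}

## canonical_kmer without revalidation, hot-path version used on window sets
## that were already alphabet-checked and N-filtered.
canonicalize_fast <- function(w) {
  u <- unique(w)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(u)))
  cu <- ifelse(u <= rc, u, rc)
  cu[match(w, u)]
}

#' K-mer feature specification
#'
#' Describes which k-mer lengths are used as model features and how strand is
#' handled. With `canonicalize = TRUE` (the default) a k-mer and its reverse
#' complement are merged into one canonical feature; this both implements
#' both-strand detection and avoids exactly collinear columns in the design
#' matrix. Mixed word lengths are supported because informative k-mers can be
#' longer than the bulk of frequent short words.
#'
#' @param k Integer vector of word lengths (sorted, deduplicated; each >= 1).
#' @param canonicalize Merge each k-mer with its reverse complement into a
#'   single canonical feature.
#' @param both_strands Test presence of a k-mer on both strands.
#' @return An object of class `kmer_spec`.
#' @export
kmer_spec <- function(k = 4:8, canonicalize = TRUE, both_strands = TRUE) {
  k <- sort(unique(as.integer(k)))
  if (length(k) == 0L || anyNA(k) || any(k < 1L)) {
    stop("`k` must contain positive integer word lengths")
  }
  structure(list(k = k, canonicalize = isTRUE(canonicalize),
                 both_strands = isTRUE(both_strands)),
            class = "kmer_spec")
}

#' @export
print.kmer_spec <- function(x, ...) {
  cat("k-mer spec: k = {", paste(x$k, collapse = ", "), "}, ",
      if (x$canonicalize) "canonical features" else "raw features",
      ", ", if (x$both_strands) "both strands" else "forward strand only",
      "\n", sep = "")
  invisible(x)
}

## All length-k windows of `seqs`, as a data.table(read = id, kmer = window).
## Windows containing N are dropped. `ids` lets callers attach both strands of
## a read to the same read id.
kmer_windows <- function(seqs, k, ids = seq_along(seqs)) {
  lens <- nchar(seqs)
  max_start <- max(lens) - k + 1L
  if (length(seqs) == 0L || is.na(max_start) || max_start < 1L) {
    return(data.table(read = integer(0), kmer = character(0)))
  }
  idx <- vector("list", max_start)
  win <- vector("list", max_start)
  for (s in seq_len(max_start)) {
    ok <- which(lens >= s + k - 1L)
    if (!length(ok)) next
    idx[[s]] <- ids[ok]
    win[[s]] <- substring(seqs[ok], s, s + k - 1L)
  }
  dt <- data.table(read = unlist(idx, use.names = FALSE),
                   kmer = unlist(win, use.names = FALSE))
  dt[!grepl("N", kmer, fixed = TRUE)]
}

#' K-mers present in a sequence
#'
#' Returns the set of (canonical) k-mers, over every word length in `spec`,
#' that occur as a substring of `s` on either strand. Windows containing `N`
#' contribute nothing. A sequence shorter than `k` yields no k-mers of that
#' length.
#'
#' @param s A single DNA sequence.
#' @param spec A [kmer_spec()].
#' @return Sorted character vector of k-mers present.
#' @examples
#' kmers_present("ACGT", kmer_spec(k = 4))
#' @export
kmers_present <- function(s, spec = kmer_spec()) {
  if (length(s) != 1L) stop("`s` must be a single sequence")
  s <- normalize_seqs(s)
  seqs <- s
  if (spec$both_strands && !spec$canonicalize) seqs <- c(s, reverse_complement(s))
  out <- character(0)
  for (k in spec$k) {
    w <- unique(kmer_windows(seqs, k)$kmer)
    if (spec$canonicalize && length(w)) w <- unique(canonicalize_fast(w))
    out <- c(out, w)
  }
  sort(unique(out))
}

#' Bound/unbound k-mer count table
#'
#' Builds the k-mer table listing, for every (canonical) k-mer observed in
#' either read set, its count among the bound (enriched) reads and among the
#' unbound (random) reads. Under the default `"presence"` counting mode a
#' k-mer is counted at most once per read, matching the binary design-matrix
#' definition; `"occurrence"` counts every window, and is intended for
#' frequency-style rankings only.
#'
#' @param bound,unbound Non-empty character vectors of reads.
#' @param spec A [kmer_spec()].
#' @param mode `"presence"` (per-read presence, default) or `"occurrence"`.
#' @return A `kmer_table`: a data.table with columns `kmer`, `k`,
#'   `count_bound`, `count_unbound`, plus attributes `n_bound_reads`,
#'   `n_unbound_reads`, `mode` and `spec`.
#' @export
build_kmer_table <- function(bound, unbound, spec = kmer_spec(),
                             mode = c("presence", "occurrence")) {
  mode <- match.arg(mode)
  if (length(bound) == 0L || length(unbound) == 0L) {
    stop("both `bound` and `unbound` read sets must be non-empty")
  }
  bound <- normalize_seqs(bound)
  unbound <- normalize_seqs(unbound)

  count_set <- function(reads) {
    seqs <- reads
    ids <- seq_along(reads)
    if (spec$both_strands && !spec$canonicalize) {
      seqs <- c(reads, reverse_complement(reads))
      ids <- c(ids, ids)
    }
    per_k <- lapply(spec$k, function(kk) {
      dt <- kmer_windows(seqs, kk, ids)
      if (nrow(dt) == 0L) {
        return(data.table(kmer = character(0), k = integer(0), n = integer(0)))
      }
      if (spec$canonicalize) dt[, kmer := canonicalize_fast(kmer)]
      if (mode == "presence") dt <- unique(dt, by = c("read", "kmer"))
      cnt <- dt[, .N, by = kmer]
      data.table(kmer = cnt$kmer, k = kk, n = cnt$N)
    })
    rbindlist(per_k)
  }

  cb <- count_set(bound)
  cu <- count_set(unbound)
  tab <- merge(cb, cu, by = c("kmer", "k"), all = TRUE, suffixes = c("_bound", "_unbound"))
  data.table::setnames(tab, c("n_bound", "n_unbound"), c("count_bound", "count_unbound"))
  tab[is.na(count_bound), count_bound := 0L]
  tab[is.na(count_unbound), count_unbound := 0L]
  setorder(tab, k, kmer)
  data.table::setattr(tab, "n_bound_reads", length(bound))
  data.table::setattr(tab, "n_unbound_reads", length(unbound))
  data.table::setattr(tab, "mode", mode)
  data.table::setattr(tab, "spec", spec)
  data.table::setattr(tab, "class", c("kmer_table", class(tab)))
  tab[]
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("k-mer table: ", nrow(x), " k-mers (k in {",
      paste(sort(unique(x$k)), collapse = ", "), "}), ",
      attr(x, "n_bound_reads"), " bound / ", attr(x, "n_unbound_reads"),
      " unbound reads, ", attr(x, "mode"), " counting\n", sep = "")
  NextMethod()
  invisible(x)
}
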