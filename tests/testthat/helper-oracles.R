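# Brute-force reference implementations, deliberately naive and independent
# of the package internals, used to cross-check the fast paths.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n, len) {
  vapply(seq_len(n),
         function(i) paste(sample(BASES, len, replace = TRUE), collapse = ""),
         character(1))
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# Naive window-by-window substring test (no regex machinery).
oracle_contains <- function(s, w) {
  k <- nchar(w)
  L <- nchar(s)
  if (L < k) return(FALSE)
  for (i in seq_len(L - k + 1)) {
    if (substr(s, i, i + k - 1) == w) return(TRUE)
  }
  FALSE
}

oracle_present_both <- function(s, w) {
  oracle_contains(s, w) || oracle_contains(s, oracle_revcomp(w))
}

all_kmers <- function(k) {
  apply(expand.grid(rep(list(BASES), k), stringsAsFactors = FALSE),
        1, paste, collapse = "")
}

# Construct a kmer_table with arbitrary counts, for exercising select_top.
make_kmer_table <- function(kmer, count_bound, count_unbound,
                            n_bound = sum(count_bound),
                            n_unbound = sum(count_unbound)) {
  tab <- data.table::data.table(kmer = kmer, k = nchar(kmer),
                                count_bound = as.integer(count_bound),
                                count_unbound = as.integer(count_unbound))
  data.table::setorder(tab, k, kmer)
  data.table::setattr(tab, "n_bound_reads", n_bound)
  data.table::setattr(tab, "n_unbound_reads", n_unbound)
  data.table::setattr(tab, "mode", "presence")
  data.table::setattr(tab, "spec", kmer_spec(sort(unique(nchar(kmer)))))
  data.table::setattr(tab, "class", c("kmer_table", class(tab)))
  tab[]
}

# Full-sort oracle for top-n selection.
oracle_top_n <- function(tab, criterion, n, pseudocount = 1) {
  df <- as.data.frame(tab)
  stat <- switch(criterion,
    frequency = df$count_bound + df$count_unbound,
    difference = df$count_bound - df$count_unbound,
    fold_change = (df$count_bound + pseudocount) / (df$count_unbound + pseudocount))
  df$kmer[order(-stat, df$k, df$kmer)][seq_len(min(n, nrow(df)))]
}

# Exhaustive sweep over all candidate thresholds (every distinct score plus
# one above the maximum), rule score >= t => positive.
oracle_best_accuracy <- function(scores, labels) {
  cand <- c(sort(unique(scores)), max(scores) + 1)
  max(vapply(cand, function(t) mean((scores >= t) == (labels == 1)), numeric(1)))
}

# Pairwise enumeration of the Mann-Whitney AUC (ties count one half).
oracle_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Enumerate every window on both strands and sum log-odds terms.
oracle_pwm_max <- function(x, s, both_strands = TRUE) {
  L <- nrow(x$probs)
  strands <- if (both_strands) c(s, oracle_revcomp(s)) else s
  best <- -Inf
  for (q in strands) {
    n <- nchar(q)
    if (n < L) next
    for (i in seq_len(n - L + 1)) {
      win <- strsplit(substr(q, i, i + L - 1), "")[[1]]
      if (any(win == "N")) next
      sc <- 0
      for (j in seq_len(L)) {
        b <- match(win[j], BASES)
        sc <- sc + log(unname(x$probs[j, b]) / x$background[b])
      }
      if (sc > best) best <- sc
    }
  }
  if (is.finite(best)) best else NA_real_
}

# Exhaustive strand/offset search for k-mer-to-PWM alignment.
oracle_align_score <- function(x, w) {
  L <- nrow(x$probs)
  best <- -Inf
  for (ww in c(w, oracle_revcomp(w))) {
    bi <- match(strsplit(ww, "")[[1]], BASES)
    kl <- length(bi)
    for (o in (-kl + 1):(L - 1)) {
      s <- 0
      for (i in seq_len(kl)) {
        pos <- o + i
        s <- s + if (pos >= 1 && pos <= L) log(unname(x$probs[pos, bi[i]])) else log(x$background[bi[i]])
      }
      if (s > best) best <- s
    }
  }
  best
}
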