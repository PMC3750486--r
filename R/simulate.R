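## SELEX enrichment-cycle simulator and ChIP-seq-style peak generator,
## providing ground-truth data for every other module.

#' SELEX simulation configuration
#'
#' Describes one simulated SELEX experiment: a uniform random initial pool of
#' fixed-length reads, followed by `n_cycles` rounds in which reads are
#' selected with probability proportional to `exp(beta * affinity)` and
#' resampled with replacement back to the pool size (the wet protocol's
#' bind-precipitate-amplify round; resampling stands in for PCR
#' amplification). The affinity of a read comes from a planted truth model: a
#' named k-mer affinity map, a fitted `kmer_model`, or a `pwm` scored by its
#' maximum log-odds window.
#'
#' In a wet experiment the molecular pool (~10^12 molecules) is vastly larger
#' than the sequenced sample, so duplicate reads are rare even after several
#' cycles. `library_factor` reproduces that scale separation at desk scale:
#' the selection chain runs on an internal pool of
#' `library_factor * pool_size` molecules, and each cycle's read set is a
#' `pool_size` sequencing sample drawn from it. With `library_factor = 1`
#' the sequenced reads and the pool coincide, and at small pool sizes the
#' late cycles collapse onto a handful of founder molecules — an artifact of
#' the miniature pool, not of the protocol.
#'
#' The defaults emulate a mid-scale experiment: 14 nt reads (the standard
#' pool in which all 14-mers are evenly represented), 5000 sequenced reads
#' per cycle from a 50x larger molecular pool, 3 cycles, and a single
#' planted consensus (the AP-1 site TGACTCA) with selection stringency
#' `beta = 3`, which takes the consensus from its ~0.1% background
#' occurrence to a clear majority of the pool by cycle 3.
#'
#' @param read_length Read length in nt (default 14).
#' @param pool_size Number of reads sequenced per cycle (>= 1).
#' @param n_cycles Number of enrichment cycles (>= 1).
#' @param affinity Named numeric k-mer map, `kmer_model`, or `pwm`.
#' @param beta Selection stringency (> 0); weight is `exp(beta * affinity)`.
#' @param library_factor Ratio of molecular pool size to sequenced sample
#'   size (>= 1, default 50).
#' @param seed Optional integer seed; all randomness flows from it.
#' @return A `selex_config`.
#' @export
selex_config <- function(read_length = 14, pool_size = 5000, n_cycles = 3,
                         affinity = c(TGACTCA = 1), beta = 3,
                         library_factor = 50, seed = NULL) {
  if (read_length < 1L) stop("`read_length` must be >= 1")
  if (pool_size < 1L) stop("`pool_size` must be >= 1")
  if (n_cycles < 1L) stop("`n_cycles` must be >= 1")
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be > 0")
  if (!is.numeric(library_factor) || library_factor < 1) {
    stop("`library_factor` must be >= 1")
  }
  structure(list(read_length = as.integer(read_length),
                 pool_size = as.integer(pool_size),
                 n_cycles = as.integer(n_cycles),
                 affinity = affinity, beta = beta,
                 library_factor = library_factor, seed = seed),
            class = "selex_config")
}

affinity_scorer <- function(aff) {
  if (inherits(aff, "pwm")) {
    function(reads) pwm_max_scores(aff, reads)
  } else if (inherits(aff, "kmer_model")) {
    function(reads) score_sequences(aff, reads)
  } else if (is.numeric(aff) && !is.null(names(aff))) {
    m <- kmer_model(aff)
    function(reads) score_sequences(m, reads)
  } else {
    stop("`affinity` must be a pwm, a kmer_model, or a named numeric k-mer map")
  }
}

#' Simulate a SELEX experiment
#'
#' The molecular pool starts as `library_factor * pool_size` uniform random
#' molecules; each cycle the pool is redrawn with replacement, a molecule's
#' selection weight being `exp(beta * affinity(molecule))` (Boltzmann
#' selection — one round of binding, precipitation and re-amplification at
#' constant pool size). The read set reported for each cycle is a
#' `pool_size` sequencing sample from the pool at that stage. Reads a PWM
#' cannot score (shorter than the motif) get zero selection weight.
#'
#' @param config A [selex_config()].
#' @return A `selex_sim`: list with `cycles` (character vectors named
#'   `cycle0 ... cycleN`) and the generating `config` as planted truth.
#' @export
simulate_selex <- function(config = selex_config()) {
  stopifnot(inherits(config, "selex_config"))
  scorer <- affinity_scorer(config$affinity)
  with_seed(config$seed, {
    pool_n <- as.integer(round(config$library_factor * config$pool_size))
    pool <- generate_random_reads(pool_n, config$read_length)
    sequence_sample <- function(pool) {
      pool[sample.int(length(pool), config$pool_size)]
    }
    cycles <- vector("list", config$n_cycles + 1L)
    cycles[[1L]] <- sequence_sample(pool)
    for (t in seq_len(config$n_cycles)) {
      sc <- scorer(pool)
      sc[is.na(sc)] <- -Inf
      w <- exp(config$beta * (sc - max(sc[is.finite(sc)])))
      pool <- pool[sample.int(length(pool), pool_n, replace = TRUE, prob = w)]
      cycles[[t + 1L]] <- sequence_sample(pool)
    }
    names(cycles) <- paste0("cycle", 0:config$n_cycles)
    structure(list(cycles = cycles, config = config), class = "selex_sim")
  })
}

#' @export
print.selex_sim <- function(x, ...) {
  cat("simulated SELEX: ", x$config$n_cycles, " cycles, pool ",
      x$config$pool_size, " x ", x$config$read_length, " nt, beta = ",
      x$config$beta, "\n", sep = "")
  invisible(x)
}

#' Simulate reads carrying one of several dependent motif variants
#'
#' Each read receives exactly one variant, sampled by weight, planted at a
#' uniform random offset on a uniform random strand; the remaining bases are
#' uniform. With two or more dissimilar variants this creates dependencies
#' between motif positions that no single PWM can represent, which is the
#' regime in which the k-mer model has the advantage.
#'
#' @param n Number of reads.
#' @param read_length Read length in nt.
#' @param variants Character vector of motif variant strings (each must fit
#'   in `read_length`).
#' @param weights Optional sampling weights (default equal).
#' @param seed Optional integer seed.
#' @return Character vector of reads, with a `truth` attribute (data.frame
#'   of planted `variant`, `strand`, `offset` per read).
#' @export
simulate_dependent_motif_reads <- function(n, read_length, variants,
                                           weights = NULL, seed = NULL) {
  variants <- normalize_seqs(variants, what = "variant", allow_n = FALSE)
  vl <- nchar(variants)
  if (any(vl > read_length)) {
    stop("variant(s) longer than `read_length`: ",
         paste(variants[vl > read_length], collapse = ", "))
  }
  if (is.null(weights)) weights <- rep(1, length(variants))
  if (length(weights) != length(variants) || any(weights < 0) || sum(weights) == 0) {
    stop("`weights` must be non-negative with positive sum, one per variant")
  }
  with_seed(seed, {
    bg <- generate_random_reads(n, read_length)
    vi <- sample.int(length(variants), n, replace = TRUE, prob = weights)
    ins <- variants[vi]
    flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
    ins[flip] <- reverse_complement(ins[flip])
    il <- vl[vi]
    max_off <- read_length - il + 1L
    off <- pmin(1L + as.integer(floor(runif(n) * max_off)), max_off)
    reads <- paste0(substr(bg, 1L, off - 1L), ins,
                    substr(bg, off + il, read_length))
    attr(reads, "truth") <- data.frame(variant = variants[vi],
                                       strand = ifelse(flip, "-", "+"),
                                       offset = off)
    reads
  })
}

#' Simulate ChIP-seq-style peak sequences
#'
#' Positives get the motif planted (on a uniform random strand) at a uniform
#' position inside the central 50 nt window with probability
#' `planting_prob`; negatives, and unplanted positives, are uniform random.
#' This emulates true peaks carrying a binding site near the summit versus
#' randomly chosen unbound locations.
#'
#' @param n_pos,n_neg Numbers of positive and negative peaks.
#' @param peak_length Peak length in nt (default 300).
#' @param motif Planted motif (must fit within the central 50 nt).
#' @param planting_prob Probability a positive carries the motif (default 1).
#' @param seed Optional integer seed.
#' @return List with `pos` and `neg` (character vectors) and `truth`
#'   (planted motif, probability and per-positive planting indicator).
#' @export
simulate_peaks <- function(n_pos, n_neg, peak_length = 300, motif = "TGACTCA",
                           planting_prob = 1, seed = NULL) {
  motif <- normalize_seqs(motif, what = "motif", allow_n = FALSE)
  ml <- nchar(motif)
  cw <- min(50L, peak_length)
  if (ml > cw) stop("motif (", ml, " nt) must fit within the central ", cw, " nt")
  if (planting_prob < 0 || planting_prob > 1) stop("`planting_prob` must be in [0, 1]")
  with_seed(seed, {
    pos <- generate_random_reads(n_pos, peak_length)
    neg <- generate_random_reads(n_neg, peak_length)
    lo <- floor((peak_length - cw) / 2) + 1L
    plant <- runif(n_pos) < planting_prob
    k <- sum(plant)
    if (k > 0L) {
      start <- lo + pmin(as.integer(floor(runif(k) * (cw - ml + 1L))), cw - ml)
      ins <- rep(motif, k)
      flip <- sample(c(TRUE, FALSE), k, replace = TRUE)
      ins[flip] <- reverse_complement(ins[flip])
      pos[plant] <- paste0(substr(pos[plant], 1L, start - 1L), ins,
                           substr(pos[plant], start + ml, peak_length))
    }
    list(pos = pos, neg = neg,
         truth = list(motif = motif, planting_prob = planting_prob,
                      planted = plant))
  })
}
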