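test_that("PWM construction applies pseudocounts and validates rows", {
  p <- pwm_from_counts(matrix(c(10, 0, 0, 0), 1, 4), pseudocount = 1)
  expect_equal(unname(p$probs[1, ]), c(11, 1, 1, 1) / 14)
  expect_error(pwm(matrix(c(0.5, 0.5, 0, 0), 1, 4)), "pseudocount")
  expect_error(pwm(matrix(0.3, 2, 4)), "sum to 1")
  expect_error(pwm(matrix(0.25, 2, 3)), "4 columns")
  inst <- pwm_from_instances(c("ACGT", "ACGA"))
  expect_equal(unname(inst$probs[1, ]), c(3, 1, 1, 1) / 6)
  expect_equal(unname(inst$probs[4, ]), c(2, 1, 1, 2) / 6)
  expect_identical(pwm_consensus(pwm_from_instances("TGACTCA")), "TGACTCA")
})

test_that("MEME, JASPAR and plain-matrix files parse to the same PWM", {
  counts <- matrix(c(8, 1, 1, 0,
                     0, 9, 1, 0,
                     2, 2, 3, 3), 3, 4, byrow = TRUE)
  jaspar <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0000.1 toy",
               sprintf("A [ %s ]", paste(counts[, 1], collapse = " ")),
               sprintf("C [ %s ]", paste(counts[, 2], collapse = " ")),
               sprintf("G [ %s ]", paste(counts[, 3], collapse = " ")),
               sprintf("T [ %s ]", paste(counts[, 4], collapse = " "))), jaspar)
  plain <- withr::local_tempfile(fileext = ".txt")
  writeLines(apply(counts, 1, paste, collapse = " "), plain)
  p1 <- read_pwm(jaspar)
  p2 <- read_pwm(plain)
  expect_equal(p1$probs, p2$probs)
  expect_equal(unname(p1$probs[1, ]), c(9, 2, 2, 1) / 14)

  meme <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "MOTIF toy",
               "letter-probability matrix: alength= 4 w= 2",
               " 0.970000 0.010000 0.010000 0.010000",
               " 0.010000 0.010000 0.010000 0.970000"), meme)
  p3 <- read_pwm(meme)
  expect_equal(unname(p3$probs[, 1]), c(0.97, 0.01))
  expect_identical(pwm_consensus(p3), "AT")

  bad <- withr::local_tempfile()
  writeLines(c("0.5 0.5 0.1", "0.2 0.2 0.2"), bad)
  expect_error(read_pwm(bad), "L x 4|4 x L")
})

test_that("PWM write/read round-trips probabilities to 1e-12", {
  set.seed(61)
  raw <- matrix(rexp(6 * 4), 6, 4) + 0.05
  p <- pwm(raw / rowSums(raw))
  f <- withr::local_tempfile(fileext = ".txt")
  write_pwm(p, f)
  p2 <- read_pwm(f)
  expect_equal(p2$probs, p$probs, tolerance = 1e-12)
  fm <- withr::local_tempfile(fileext = ".meme")
  write_pwm(p, fm, format = "meme")
  expect_equal(read_pwm(fm)$probs, p$probs, tolerance = 1e-12)
})

test_that("max-score scanning matches the window/strand oracle", {
  unif <- pwm(matrix(0.25, 3, 4))
  expect_equal(scan_max_score(unif, "ACGTACGT"), 0)

  one <- pwm(matrix(c(1 - 3e-9, 1e-9, 1e-9, 1e-9), 1, 4))
  expect_equal(scan_max_score(one, "CA", both_strands = FALSE), log((1 - 3e-9) / 0.25),
               tolerance = 1e-6)
  expect_error(scan_max_score(one, ""), "shorter than the motif")

  set.seed(63)
  for (i in 1:10) {
    L <- sample(2:5, 1)
    raw <- matrix(rexp(L * 4), L, 4) + 0.02
    p <- pwm(raw / rowSums(raw))
    s <- rand_dna(1, sample(L:15, 1))
    expect_equal(scan_max_score(p, s), oracle_pwm_max(p, s), tolerance = 1e-12)
    expect_equal(scan_max_score(p, s), scan_max_score(p, reverse_complement(s)))
  }
})

test_that("PWM classification recovers a planted one-hot motif and ties at uniform", {
  reads_pos <- simulate_dependent_motif_reads(80, 12, "TGACTCA", seed = 65)
  reads_neg <- generate_random_reads(200, 12, seed = 66)
  reads_neg <- reads_neg[!grepl("TGACTCA", reads_neg) & !grepl("TGAGTCA", reads_neg)][1:80]
  hot <- pwm_from_instances("TGACTCA", pseudocount = 0.01)
  res <- classify_with_pwm(hot, reads_pos[1:40], reads_neg[1:40],
                           reads_pos[41:80], reads_neg[41:80])
  expect_equal(res$value, 1.0)

  unif <- pwm(matrix(0.25, 4, 4))
  res_u <- classify_with_pwm(unif, reads_pos[1:40], reads_neg[1:40],
                             reads_pos[41:80], reads_neg[41:80])
  expect_equal(res_u$value, 0.5)  # all scores tie; tie-positive rule -> prevalence

  expect_warning(
    classify_with_pwm(hot, reads_pos[1:40], reads_neg[1:40],
                      c(reads_pos[41:80], "ACG"), reads_neg[41:80]),
    "skipped")
})

test_that("k-mer alignment to a PWM finds the consensus offset and is strand symmetric", {
  p <- pwm_from_instances(c("TGACTCA", "TGACTCA", "TGAGTCA"))
  al <- align_kmers_to_pwm(p, "TGACTCA")
  expect_identical(al$strand, "+")
  expect_identical(al$offset, 0L)

  set.seed(67)
  kms <- rand_dna(8, 5)
  al2 <- align_kmers_to_pwm(p, kms)
  al2rc <- align_kmers_to_pwm(p, reverse_complement(kms))
  expect_equal(al2$alignment_score, al2rc$alignment_score)
  for (i in seq_along(kms)) {
    expect_equal(al2$alignment_score[i], oracle_align_score(p, kms[i]),
                 tolerance = 1e-12)
  }
})
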