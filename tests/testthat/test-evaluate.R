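test_that("split_reads partitions reads 7:3, reproducibly", {
  reads <- rand_dna(10, 8)
  sp <- split_reads(reads, seed = 1)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  expect_setequal(c(sp$train, sp$test), reads)
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- split_reads(reads, seed = 1)
  expect_identical(sp, sp2)
  expect_error(split_reads(reads, train_fraction = 1.2), "train_fraction")
  expect_error(split_reads("ACGT"), "at least 2")
})

test_that("random negative reads are uniform over the alphabet", {
  r <- generate_random_reads(5, 14, seed = 2)
  expect_length(r, 5)
  expect_true(all(nchar(r) == 14))
  expect_identical(r, generate_random_reads(5, 14, seed = 2))
  big <- generate_random_reads(100000, 14, seed = 3)
  freq <- table(strsplit(paste(big, collapse = ""), "")[[1]]) / (100000 * 14)
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("optimal_threshold maximizes accuracy and matches an exhaustive sweep", {
  th <- optimal_threshold(c(3, 2, 1, 0), c(1, 1, 0, 0))
  expect_equal(th$threshold, 1.5)
  expect_equal(th$accuracy, 1.0)
  th2 <- optimal_threshold(c(1, 1), c(1, 0))
  expect_equal(th2$accuracy, 0.5)
  expect_error(optimal_threshold(c(1, 2), c(1, 1)), "both classes")

  set.seed(51)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    got <- optimal_threshold(scores, labels)
    expect_equal(got$accuracy, oracle_best_accuracy(scores, labels))
    # the returned threshold actually achieves the returned accuracy
    expect_equal(mean((scores >= got$threshold) == (labels == 1)), got$accuracy)
    # never worse than the majority-class rule on training data
    expect_gte(got$accuracy, max(mean(labels), 1 - mean(labels)))
  }
})

test_that("normal-approximation accuracy CI matches the closed form", {
  ci <- accuracy_ci(50, 100)
  expect_equal(unname(ci), c(0.5, 0.4020018, 0.5979982), tolerance = 1e-6)
  expect_equal(unname(accuracy_ci(100, 100)), c(1, 1, 1))
  w1 <- accuracy_ci(60, 100)
  w2 <- accuracy_ci(600, 1000)
  expect_lt(w2[["ci_high"]] - w2[["ci_low"]], w1[["ci_high"]] - w1[["ci_low"]])
})

test_that("AUC is the Mann-Whitney pair statistic with ties counted half", {
  expect_equal(auc(c(2, 3), c(0, 1)), 1.0)
  expect_equal(auc(c(3, 1), c(2, 0)), 0.75)
  expect_equal(auc(1, 1), 0.5)
  expect_error(auc(numeric(0), 1), "non-empty")
  set.seed(53)
  for (i in 1:20) {
    pos <- round(rnorm(sample(3:15, 1)), 1)
    neg <- round(rnorm(sample(3:15, 1)), 1)
    expect_equal(auc(pos, neg), oracle_auc(pos, neg))
    expect_equal(auc(pos, neg) + auc(neg, pos), 1)
    # invariance under a strictly monotone transform
    expect_equal(auc(exp(pos), exp(neg)), auc(pos, neg))
  }
})

test_that("Mann-Whitney AUC CI follows the Hanley-McNeil variance", {
  ci <- auc_ci_mann_whitney(0.8, 50, 50)
  expect_equal(unname(ci), c(0.7127773, 0.8872227), tolerance = 1e-6)
  sym <- auc_ci_mann_whitney(0.5, 200, 200)
  expect_equal(0.5 - sym[["ci_low"]], sym[["ci_high"]] - 0.5, tolerance = 1e-12)
  wide <- auc_ci_mann_whitney(0.7, 50, 50)
  narrow <- auc_ci_mann_whitney(0.7, 100, 100)
  expect_lt(narrow[["ci_high"]] - narrow[["ci_low"]],
            wide[["ci_high"]] - wide[["ci_low"]])
  perfect <- auc_ci_mann_whitney(1.0, 30, 30)
  expect_equal(unname(perfect), c(1, 1))
})

test_that("peak evaluation scores full regions or center windows", {
  m <- kmer_model(c(TGACTCA = 1))
  pk <- simulate_peaks(60, 60, peak_length = 120, motif = "TGACTCA",
                       planting_prob = 1, seed = 55)
  res <- evaluate_chipseq(m, pk$pos, pk$neg, region_mode = "center",
                          center_width = 50)
  expect_equal(res$value, 1.0)
  expect_equal(res$ci_low, 1.0)

  zero <- kmer_model(c(TGACTCA = 0))
  res0 <- evaluate_chipseq(zero, pk$pos, pk$neg)
  expect_equal(res0$value, 0.5)

  # a center window as wide as the peak is the full region
  rc <- evaluate_chipseq(m, pk$pos, pk$neg, region_mode = "center",
                         center_width = 120)
  rf <- evaluate_chipseq(m, pk$pos, pk$neg, region_mode = "full")
  expect_equal(rc$value, rf$value)

  # sequences shorter than the window are skipped with a warning
  expect_warning(
    evaluate_chipseq(m, c(pk$pos, "ACGTACGT"), pk$neg,
                     region_mode = "center", center_width = 50),
    "skipped")
})

test_that("center windows favour centrally planted motifs over noisy flanks", {
  set.seed(57)
  m <- kmer_model(c(TGACTCA = 1, AACGG = 0.5, CATGC = 0.5, GGATA = 0.5))
  pk <- simulate_peaks(150, 150, peak_length = 300, motif = "TGACTCA",
                       planting_prob = 1, seed = 59)
  a_center <- evaluate_chipseq(m, pk$pos, pk$neg, region_mode = "center",
                               center_width = 100)$value
  a_full <- evaluate_chipseq(m, pk$pos, pk$neg, region_mode = "full")$value
  expect_gte(a_center, a_full)
})
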