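test_that("design matrix entries follow the both-strand presence rule", {
  A <- build_design_matrix(c("AAAA", "CCCC"), c("AAAA", "CCCC"), kmer_spec(4))
  expect_equal(unname(as.matrix(A)), diag(2))

  A0 <- build_design_matrix("ACGTACGT", character(0))
  expect_identical(dim(A0), c(1L, 0L))

  expect_error(build_design_matrix("ACGT", c("ACGT", "ACGT"), kmer_spec(4)),
               "duplicate")
  expect_error(build_design_matrix("ACGT", "TTTT", kmer_spec(4)), "canonical")

  set.seed(21)
  reads <- rand_dna(20, 12)
  kms <- sample(sort(unique(canonical_kmer(all_kmers(5)))), 10)
  A <- build_design_matrix(reads, kms, kmer_spec(5))
  oracle <- outer(reads, kms, Vectorize(function(s, w) as.numeric(oracle_present_both(s, w))))
  expect_equal(unname(as.matrix(A)), oracle)
})

test_that("fit_affinities solves the linear system and recovers planted affinities", {
  A <- Matrix::sparseMatrix(i = 1:2, j = 1:2, x = 1, dims = c(2, 2),
                            dimnames = list(NULL, c("AAAA", "CCCC")))
  m <- fit_affinities(A, c(1, 0), ridge_lambda = 0, spec = kmer_spec(4))
  expect_equal(unname(m$affinities), c(1, 0))
  expect_equal(m$meta$residual_norm, 0)

  # noise-free planted system: b = A x_true, exact recovery at lambda = 0
  set.seed(33)
  spec <- kmer_spec(4)
  kms <- sort(sample(unique(canonical_kmer(all_kmers(4))), 3))
  reads <- rand_dna(40, 12)
  A <- build_design_matrix(reads, kms, spec)
  stopifnot(qr(as.matrix(A))$rank == 3)
  x_true <- c(0.5, -0.25, 1.0)
  b <- as.numeric(A %*% x_true)
  m <- fit_affinities(A, b, ridge_lambda = 0, spec = spec)
  expect_equal(unname(m$affinities), x_true, tolerance = 1e-8)
  # normal equations hold
  expect_equal(as.numeric(Matrix::crossprod(A, A %*% m$affinities)),
               as.numeric(Matrix::crossprod(A, b)), tolerance = 1e-8)
})

test_that("ridge penalty shrinks the solution monotonically", {
  set.seed(5)
  reads <- rand_dna(30, 10)
  kms <- sort(sample(unique(canonical_kmer(all_kmers(3))), 5))
  A <- build_design_matrix(reads, kms, kmer_spec(3))
  b <- rep(c(1, 0), length.out = 30)
  norms <- vapply(c(1e-9, 1, 10, 1000), function(lam) {
    sqrt(sum(fit_affinities(A, b, ridge_lambda = lam, spec = kmer_spec(3))$affinities^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("rank deficiency errors without ridge and shrinks to zero with it", {
  reads <- c("CCCC", "GGGG", "CCGG")
  # AAAA never occurs: its column is all zero
  expect_error(
    fit_affinities(build_design_matrix(reads, c("AAAA", "CCCC"), kmer_spec(4)),
                   c(1, 0, 1), ridge_lambda = 0, spec = kmer_spec(4)),
    "rank deficient")
  m <- fit_affinities(build_design_matrix(reads, c("AAAA", "CCCC"), kmer_spec(4)),
                      c(1, 0, 1), ridge_lambda = 1e-6, spec = kmer_spec(4))
  expect_lt(abs(m$affinities[["AAAA"]]), 1e-9)
  expect_warning(
    fit_affinities(build_design_matrix(c("ACGTAC", "GTTTTA"),
                                       c("AAAA", "ACGT", "AAC"), kmer_spec(3:4)),
                   c(1, 0), ridge_lambda = 1e-6, spec = kmer_spec(3:4)),
    "underdetermined")
  expect_error(fit_affinities(A = build_design_matrix("ACGT", "ACGT", kmer_spec(4)),
                              b = c(1), ridge_lambda = 1e-6), "both classes")
})

test_that("scoring is the affinity sum over present k-mers, matching A %*% x", {
  m <- kmer_model(c(AAC = 2, CCG = -1))
  expect_equal(score_sequence(m, "AACGG"), 1.0)
  empty <- kmer_model(setNames(numeric(0), character(0)))
  expect_equal(score_sequence(empty, "ACGTACGT"), 0)

  set.seed(41)
  spec <- kmer_spec(c(3, 4))
  reads <- rand_dna(30, 14)
  kms <- sort(unique(canonical_kmer(c(all_kmers(3)[sample(64, 6)],
                                      all_kmers(4)[sample(256, 6)]))))
  A <- build_design_matrix(reads, kms, spec)
  m <- fit_affinities(A, rep(c(1, 0), 15), ridge_lambda = 1e-6, spec = spec)
  expect_equal(score_sequences(m, reads), as.numeric(A %*% m$affinities),
               tolerance = 1e-12)
})

test_that("scores are strand symmetric and saturate on repeated occurrences", {
  set.seed(43)
  m <- kmer_model(setNames(rnorm(5), c("AAC", "ACG", "AGT", "CCG", "AGG")))
  s <- rand_dna(20, 15)
  expect_equal(score_sequences(m, s), score_sequences(m, reverse_complement(s)))
  one <- kmer_model(c(AAC = 2))
  expect_equal(score_sequence(one, "AACTGG"), score_sequence(one, "AACAAC"))
})

test_that("model save/load round-trips at full float precision", {
  set.seed(47)
  reads <- rand_dna(20, 12)
  kms <- sort(sample(unique(canonical_kmer(all_kmers(4))), 6))
  A <- build_design_matrix(reads, kms, kmer_spec(4))
  m <- fit_affinities(A, rep(c(1, 0), 10), ridge_lambda = 1e-6, spec = kmer_spec(4))
  f <- withr::local_tempfile(fileext = ".tsv")
  save_kmer_model(m, f)
  m2 <- load_kmer_model(f)
  expect_identical(m2$kmers, m$kmers)
  expect_identical(m2$affinities, m$affinities)
  expect_identical(m2$spec$k, m$spec$k)
  expect_identical(m2$ridge_lambda, m$ridge_lambda)
  expect_identical(m2$meta$residual_norm, m$meta$residual_norm)
})
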