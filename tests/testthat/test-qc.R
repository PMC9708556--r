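test_that("the Anscombe transform matches its closed form and is monotone", {
  expect_equal(anscombe(0), 2 * sqrt(3 / 8), tolerance = 1e-12)
  expect_equal(anscombe(0), 1.224745, tolerance = 1e-6)
  expect_equal(anscombe(1), 2.345208, tolerance = 1e-6)
  x <- sort(sample(0:500, 50))
  expect_true(all(diff(anscombe(x)) > 0))
  expect_error(anscombe(-1), ">= 0")
})

test_that("identical case/control size distributions are retained", {
  sizes <- matrix(rep(c(1, 2, 3, 4, 1, 2, 3, 4), 2), nrow = 2, byrow = TRUE)
  colnames(sizes) <- c(sprintf("case%03d", 1:4), sprintf("ctrl%03d", 1:4))
  mat <- toy_matrix(sizes)
  res <- filter_batch_loci(mat, toy_samples(4, 4))
  expect_identical(res$report$status, rep("retained", 2))
  expect_true(all(res$report$p_value == 1))
})

test_that("a batch-shifted locus is removed at the default alpha", {
  set.seed(101)
  x <- exp(rnorm(50, log(2), 0.2))        # cases, shifted x1.5
  y <- exp(rnorm(50, log(2), 0.2))        # controls
  sizes <- matrix(c(x * 1.5, y), nrow = 1)
  colnames(sizes) <- c(sprintf("case%03d", 1:50), sprintf("ctrl%03d", 1:50))
  res <- filter_batch_loci(toy_matrix(sizes), toy_samples(50, 50))
  expect_identical(res$report$status, "removed")
  expect_identical(nrow(res$matrix$loci), 0L)
})

test_that("the locus filter is symmetric in cohort labels", {
  set.seed(7)
  sizes <- matrix(exp(rnorm(40, log(2), 0.3)), nrow = 2)
  sizes[2, 1:10] <- sizes[2, 1:10] * 2
  colnames(sizes) <- c(sprintf("case%03d", 1:10), sprintf("ctrl%03d", 1:10))
  mat <- toy_matrix(sizes)
  s1 <- toy_samples(10, 10)
  s2 <- s1
  s2$cohort <- ifelse(s1$cohort == "case", "control", "case")
  r1 <- filter_batch_loci(mat, s1)
  r2 <- filter_batch_loci(mat, s2)
  expect_identical(r1$report$status, r2$report$status)
  expect_equal(r1$report$p_value, r2$report$p_value, tolerance = 1e-12)
})

test_that("loci observed in one cohort only are retained as untestable", {
  sizes <- matrix(c(1.5, 2.5, NA, NA), nrow = 1)
  colnames(sizes) <- c("case001", "case002", "ctrl001", "ctrl002")
  res <- filter_batch_loci(toy_matrix(sizes), toy_samples(2, 2))
  expect_identical(res$report$status, "untestable")
  expect_identical(nrow(res$matrix$loci), 1L)
})

test_that("locus filter input validation", {
  sizes <- matrix(1, 1, 2, dimnames = list(NULL, c("case001", "ctrl001")))
  mat <- toy_matrix(sizes)
  expect_error(filter_batch_loci(mat, toy_samples(2, 0)), "cohort")
  empty <- size_matrix(mat$loci[0, ], mat$samples, mat$sizes[0, , drop = FALSE])
  expect_error(filter_batch_loci(empty, toy_samples(1, 1)), "empty")
})

test_that("sample outlier exclusion follows the either-axis 3 SD rule", {
  counts <- stats::setNames(rep(100L, 10), sprintf("s%02d", 1:10))
  rep0 <- flag_outlier_samples(counts, counts)
  expect_false(any(rep0$excluded))  # zero spread: nobody excluded

  # extreme on the TRE-count axis only (n large enough that one outlier
  # cannot mask itself by inflating the SD)
  set.seed(1)
  ids <- sprintf("s%02d", 1:25)
  loci_counts <- stats::setNames(sample(97:104, 25, replace = TRUE), ids)
  tre_counts <- stats::setNames(c(sample(1:4, 24, replace = TRUE), 80L), ids)
  rep1 <- flag_outlier_samples(loci_counts, tre_counts)
  expect_identical(rep1$sample_id[rep1$excluded], "s25")

  expect_error(flag_outlier_samples(counts[1:2]), "3 samples")
})

test_that("the seeded outlier fixture is excluded by the full QC pass", {
  cfg <- small_sim_config(seed = 31, outlier_sample_count = 1L)
  m <- simulate_annotation(cfg)
  co <- simulate_cohort(cfg, m)
  qc <- run_qc(co$matrix, co$samples)
  expect_identical(qc$sample_report$sample_id[qc$sample_report$excluded],
                   co$truth$outlier_samples)
})

test_that("size concordance is a Spearman correlation with exact small-n p", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4)
  expect_equal(size_concordance(x, 2 * x)$rho, 1)
  expect_equal(size_concordance(x, max(x) - x)$rho, -1)
  const <- size_concordance(x, rep(2, 5))
  expect_true(const$flagged)
  expect_true(is.na(const$rho))
  expect_error(size_concordance(x, x[1:3]), "length mismatch")

  set.seed(12)
  for (i in 1:5) {
    a <- sample(seq(1, 9, by = 0.5), 5)
    b <- sample(seq(1, 9, by = 0.5), 5)
    sc <- size_concordance(a, b)
    expect_equal(sc$p, spearman_enum_p(a, b), tolerance = 1e-10)
  }
})

test_that("under a null generator the locus filter removes about alpha", {
  set.seed(55)
  removed <- 0L; tested <- 0L
  for (r in 1:40) {
    sizes <- matrix(exp(rnorm(25 * 60, log(2), 0.25)), nrow = 25)
    colnames(sizes) <- c(sprintf("case%03d", 1:30), sprintf("ctrl%03d", 1:30))
    res <- filter_batch_loci(toy_matrix(sizes), toy_samples(30, 30))
    removed <- removed + sum(res$report$status == "removed")
    tested <- tested + sum(res$report$status != "untestable")
  }
  rate <- removed / tested
  ci <- stats::binom.test(removed, tested, p = 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})
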