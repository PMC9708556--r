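test_that("locus mode rounds to the bin and breaks ties to the smallest", {
  expect_equal(locus_mode(c(2.0, 2.0, 3.0)), 2.0)
  expect_equal(locus_mode(c(1.0, 2.0)), 1.0)
  expect_equal(locus_mode(c(2.004, 1.996, 5.0), mode_bin = 0.01), 2.0)
  expect_error(locus_mode(numeric()), "no observed sizes")
})

test_that("dbscan_1d reproduces constructed cluster/noise splits", {
  x <- c(rep(1.0, 11), 10.0)
  lab <- dbscan_1d(x, eps = 2, min_pts = 11)
  expect_identical(lab, c(rep(1L, 11), 0L))

  x <- c(rep(1.0, 10), 10.0)   # below the core threshold
  expect_identical(dbscan_1d(x, eps = 2, min_pts = 11), rep(0L, 11))

  expect_error(dbscan_1d(1:3, eps = 0, min_pts = 2), "eps")
})

test_that("dbscan_1d equals the brute-force neighbor-graph oracle", {
  set.seed(202)
  for (i in 1:300) {
    n <- sample(2:30, 1)
    x <- round(runif(n, 0, 10), 2)
    eps <- runif(1, 0.05, 3)
    min_pts <- sample(2:8, 1)
    expect_identical(dbscan_1d(x, eps, min_pts), dbscan_oracle(x, eps, min_pts),
                     info = sprintf("i=%d n=%d eps=%.3f min_pts=%d",
                                    i, n, eps, min_pts))
  }
})

test_that("a planted outlier is called; tight clusters yield no calls", {
  set.seed(17)
  bg <- exp(rnorm(100, log(2), 0.15))
  sizes <- matrix(c(bg, 10), nrow = 1)
  colnames(sizes) <- sprintf("s%03d", 1:101)
  calls <- call_expansions(toy_matrix(sizes))
  expect_identical(calls$sample_id, "s101")

  sizes2 <- matrix(bg, nrow = 1, dimnames = list(NULL, sprintf("s%03d", 1:100)))
  expect_identical(nrow(call_expansions(toy_matrix(sizes2))), 0L)
})

test_that("low-side noise points are never called (upper tail only)", {
  set.seed(18)
  bg <- exp(rnorm(100, log(5), 0.05))
  sizes <- matrix(c(bg, 0.01), nrow = 1)
  colnames(sizes) <- sprintf("s%03d", 1:101)
  calls <- call_expansions(toy_matrix(sizes))
  expect_identical(nrow(calls), 0L)
})

test_that("loci with no cluster make every observed sample a candidate", {
  sizes <- matrix(c(1, 5, 20, rep(NA, 3)), nrow = 1)
  colnames(sizes) <- sprintf("s%03d", 1:6)
  calls <- call_expansions(toy_matrix(sizes), caller_params(min_pts = 11))
  expect_setequal(calls$sample_id, c("s001", "s002", "s003"))
})

test_that("calling is invariant to locus and sample order", {
  cfg <- small_sim_config(seed = 6)
  co <- simulate_cohort(cfg, simulate_annotation(cfg))
  mat <- co$matrix
  set.seed(1)
  ro <- sample(nrow(mat$loci)); coix <- sample(length(mat$samples))
  perm <- size_matrix(mat$loci[ro, ], mat$samples[coix],
                      mat$sizes[ro, coix, drop = FALSE])
  c1 <- call_expansions(mat)
  c2 <- call_expansions(perm)
  expect_identical(c1, c2)
})

test_that("population frequency and the rarity boundary", {
  samples <- toy_samples(1, 0, 2504)
  ref_ids <- samples$sample_id[samples$cohort == "reference"]
  calls13 <- do.call(rbind, lapply(c("case001", ref_ids[1:13]), function(s)
    make_call("chr1", 100L, 150L, sample_id = s)))
  out <- population_frequency(calls13[, 1:7], samples)
  expect_equal(unique(out$population_frequency), 13 / 2504, tolerance = 1e-12)
  expect_equal(round(unique(out$population_frequency), 5), 0.00519)
  expect_false(any(out$rare))

  calls12 <- calls13[1:13, ]
  out12 <- population_frequency(calls12[, 1:7], samples)
  expect_equal(unique(out12$population_frequency), 12 / 2504, tolerance = 1e-12)
  expect_true(all(out12$rare))

  out0 <- population_frequency(make_call("chr1", 1L, 51L)[, 1:7], samples)
  expect_equal(out0$population_frequency, 0)
  expect_true(out0$rare)

  expect_error(population_frequency(calls13, toy_samples(2, 2, 0)),
               "reference cohort")
})

test_that("lowering the frequency cutoff never enlarges the rare set", {
  cfg <- small_sim_config(seed = 8)
  co <- simulate_cohort(cfg, simulate_annotation(cfg))
  calls <- call_expansions(co$matrix)
  cuts <- c(0.1, 0.05, 0.02, 0.005, 0.001)
  prev <- NULL
  for (ct in cuts) {
    rare <- population_frequency(calls, co$samples, ct)
    ids <- paste(rare$sample_id, rare$locus_id)[rare$rare]
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("region merging is single-linkage within the merge distance", {
  calls <- rbind(make_call("chr1", 1000L, 1050L),
                 make_call("chr1", 1150L, 1200L))   # 100 bp apart
  expect_identical(nrow(merge_regions(calls, 500L)), 1L)

  calls2 <- rbind(make_call("chr1", 1000L, 1050L),
                  make_call("chr2", 1000L, 1050L))
  expect_identical(nrow(merge_regions(calls2, 500L)), 2L)

  chain <- rbind(make_call("chr1", 1000L, 1050L),
                 make_call("chr1", 1450L, 1500L),
                 make_call("chr1", 1900L, 1950L))  # 400 bp gaps
  reg <- merge_regions(chain, 500L)
  expect_identical(nrow(reg), 1L)
  expect_identical(reg$n_loci, 3L)
  expect_identical(reg$start, 1000L)
  expect_identical(reg$end, 1950L)

  expect_identical(nrow(merge_regions(chain[0, ], 500L)), 0L)
})

test_that("the parameter grid search selects the strongest exonic signal", {
  cfg <- small_sim_config(seed = 19)
  m <- simulate_annotation(cfg)
  co <- simulate_cohort(cfg, m)

  one <- optimize_parameters(co$matrix, co$samples, m,
                             data.frame(min_pts = 11, eps_multiplier = 2,
                                        freq_cutoff = 0.05))
  expect_true(one$selected)

  # second grid point so strict that no cluster forms anywhere and nothing
  # is rare: degenerate burden tests score z = 0 on both classes
  two <- optimize_parameters(co$matrix, co$samples, m,
                             data.frame(min_pts = c(11, 400),
                                        eps_multiplier = 2,
                                        freq_cutoff = 0.05))
  expect_identical(sum(two$selected), 1L)
  expect_true(two$selected[1])
  expect_identical(two$z_exonic[2], 0)
  expect_error(optimize_parameters(co$matrix, co$samples, m,
                                   data.frame(min_pts = integer(),
                                              eps_multiplier = numeric(),
                                              freq_cutoff = numeric())),
               "empty")
})
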