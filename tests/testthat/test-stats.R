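annotated_call <- function(sample_id, element_class = "intron",
                           exon_proximal = FALSE, contig = "chr1",
                           start = 1000L) {
  data.frame(sample_id = sample_id, locus_id = sprintf("%s:%d-%d:CAG", contig,
                                                       start, start + 50L),
             contig = contig, start = start, end = start + 50L, motif = "CAG",
             size = 10, population_frequency = 0, rare = TRUE,
             element_class = element_class, gene_id = "g001",
             distance_to_exon_junction = 150L, exon_proximal = exon_proximal,
             stringsAsFactors = FALSE)
}

test_that("a constant class count gives the degenerate flagged result", {
  samples <- toy_samples(20, 20)
  fit <- tre_burden(annotated_call("case001")[0, ], samples, "exon_proximal",
                    n_permutations = 0)
  expect_identical(fit$wald_z, 0)
  expect_identical(fit$wald_p_one_sided, 0.5)
  expect_true(fit$flagged)
})

test_that("burden fit recovers a planted case excess", {
  set.seed(41)
  samples <- toy_samples(100, 100)
  carriers <- c(sprintf("case%03d", 1:20), sprintf("ctrl%03d", 1:4))
  calls <- do.call(rbind, lapply(seq_along(carriers), function(i)
    annotated_call(carriers[i], element_class = "intron",
                   exon_proximal = TRUE, start = 1000L + 100L * i)))
  fit <- tre_burden(calls, samples, "exon_proximal", n_permutations = 500,
                    params = stats_params(permutation_seed = 2))
  expect_false(fit$flagged)
  expect_gt(fit$odds_ratio, 1)
  expect_lt(fit$wald_p_one_sided, 0.05)
  expect_lt(fit$empirical_p, 0.05)
  expect_equal(fit$odds_ratio, exp(fit$beta), tolerance = 1e-12)
  expect_identical(fit$n_carriers_case, 20L)
  expect_identical(fit$n_carriers_control, 4L)
  expect_identical(unname(coef(fit)["beta"]), fit$beta)
})

test_that("sex-chromosome calls are excluded from burden counts", {
  samples <- toy_samples(10, 10)
  calls <- rbind(annotated_call("case001", contig = "chrX"),
                 annotated_call("case002", contig = "chrY"))
  fit <- tre_burden(calls, samples, "intron", n_permutations = 0)
  expect_true(fit$flagged)  # nothing autosomal left: degenerate
})

test_that("permutation p uses the add-one estimator and never hits zero", {
  samples <- toy_samples(30, 30)
  # strong case-only signal: observed z above every permuted z
  calls <- do.call(rbind, lapply(sprintf("case%03d", 1:25), function(s)
    annotated_call(s, exon_proximal = TRUE)))
  p <- permutation_p(calls, samples, "exon_proximal",
                     params = stats_params(permutation_seed = 7),
                     n_permutations = 199)
  expect_equal(p, 1 / 200, tolerance = 1e-12)

  # control-heavy signal: every permuted z at least matches the observed
  calls2 <- do.call(rbind, lapply(sprintf("ctrl%03d", 1:25), function(s)
    annotated_call(s, exon_proximal = TRUE)))
  p2 <- permutation_p(calls2, samples, "exon_proximal",
                      params = stats_params(permutation_seed = 8),
                      n_permutations = 1)
  expect_identical(p2, 1)
})

test_that("carrier proportions count samples with at least one rare call", {
  samples <- toy_samples(252, 100)
  calls <- do.call(rbind, lapply(sprintf("case%03d", 1:13), function(s)
    annotated_call(s, exon_proximal = TRUE)))
  prop <- carrier_proportion(calls, samples, "exon_proximal", "case")
  expect_equal(round(100 * prop, 2), 5.16)
  expect_equal(carrier_proportion(calls, samples, "exon_proximal", "control"),
               0)
  all_calls <- do.call(rbind, lapply(samples$sample_id[samples$cohort ==
                                                         "control"],
                                     function(s) annotated_call(s)))
  expect_equal(carrier_proportion(all_calls, samples, "all", "control"), 1)
  expect_error(carrier_proportion(calls, samples, "all", "reference"),
               "empty cohort")
})

test_that("intergenic bias correction scales the raw control proportion", {
  expect_equal(bias_corrected_control_proportion(0.02, 0.1, 0.1), 0.02)
  expect_equal(bias_corrected_control_proportion(0.02, factor = 0.6), 0.012)
  expect_equal(bias_corrected_control_proportion(0.02, 0.05, 0.10,
                                                 factor = 0.6), 0.012)
  expect_error(bias_corrected_control_proportion(0.02, 0.1, 0), "> 0")
  expect_error(bias_corrected_control_proportion(0.02), "supply")
})

test_that("attributable risk is the carrier-proportion gap in points", {
  expect_equal(attributable_risk(0.0516, 0.0120), 3.96)
  expect_equal(attributable_risk(0.3, 0.3), 0)
  expect_warning(ar <- attributable_risk(0.01, 0.02), "negative")
  expect_equal(ar, -1)
})

test_that("fisher enrichment equals hypergeometric enumeration", {
  universe <- sprintf("g%03d", 1:20)
  set <- universe[1:10]
  tre <- universe[c(1:5, 11:15)]
  res <- fisher_enrichment(set, tre, universe)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_one_sided, hyper_enrich_p(5, 5, 5, 5), tolerance = 1e-12)

  disj <- fisher_enrichment(universe[11:14], universe[1:10], universe)
  expect_lt(disj$odds_ratio, 1)
  expect_gt(disj$p_one_sided, 0.95)

  expect_error(fisher_enrichment(set, tre, character()), "empty universe")
})

test_that("enrichment suite filters, corrects, and draws similarity edges", {
  universe <- sprintf("g%04d", 1:500)
  tre <- universe[1:40]
  sets <- list(
    hitA = universe[1:40],               # identical pair: similarity 1
    hitB = universe[1:40],
    part = universe[21:70],
    null1 = universe[301:380],
    tiny = universe[1:4],                # below size bound
    huge = sprintf("x%04d", 1:1001)      # above size bound (after intersect: 0)
  )
  suite <- geneset_enrichment_suite(sets, tre, universe,
                                    stats_params(fdr_cutoff = 0.1))
  expect_setequal(suite$results$set_id, c("hitA", "hitB", "part", "null1"))
  # BH never lowers below the raw p, and is monotone after sorting
  o <- order(suite$results$p_one_sided)
  expect_true(all(diff(suite$results$q[o]) >= -1e-12))
  expect_gte(suite$results$q[o][length(o)],
             suite$results$p_one_sided[o][length(o)])
  expect_true(all(c("hitA", "hitB") %in% suite$nodes$set_id))
  pair <- suite$edges[suite$edges$set_a == "hitA" &
                        suite$edges$set_b == "hitB", ]
  expect_equal(pair$similarity, 1)
})

test_that("combined similarity weights Jaccard and overlap coefficients", {
  a <- letters[1:10]; b <- letters[6:15]   # |int| 5, |union| 15, min 10
  expect_equal(treburden:::.set_similarity(a, b, 0.5),
               0.5 * (5 / 15) + 0.5 * (5 / 10))
  expect_equal(treburden:::.set_similarity(a, a, 0.5), 1)
})

test_that("constraint comparison is one-sided for lower TRE-gene scores", {
  constraint <- data.frame(gene_id = sprintf("g%03d", 1:12),
                           score = c(0.1, 0.2, 0.3, 0.4,
                                     1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8))
  res <- constraint_comparison(sprintf("g%03d", 1:4), constraint)
  # all TRE genes rank below all others: minimal attainable one-sided p
  expect_equal(res$p, 1 / choose(12, 4), tolerance = 1e-12)
  expect_error(constraint_comparison("g001", constraint), "at least 2")

  set.seed(91)
  for (i in 1:5) {
    sc <- sample(seq(0.1, 3, by = 0.01), 8)
    con <- data.frame(gene_id = sprintf("g%03d", 1:8), score = sc)
    res <- constraint_comparison(sprintf("g%03d", 1:4), con)
    expect_equal(res$p, ranksum_less_enum(sc[1:4], sc[5:8]),
                 tolerance = 1e-12)
  }
})

test_that("subgroup comparison tests for higher burden with the flag", {
  samples <- toy_samples(20, 5)
  samples$family_history[1:8] <- TRUE
  calls <- do.call(rbind, lapply(sprintf("case%03d", 1:8), function(s)
    rbind(annotated_call(s), annotated_call(s, start = 3000L))))
  res <- subgroup_comparison(calls, samples, "family_history", "genic")
  expect_lt(res$p, 0.01)
  expect_gt(res$mean_present, res$mean_absent)
  expect_error(subgroup_comparison(calls, samples, "early_onset", "genic"),
               "non-empty")
  expect_error(subgroup_comparison(calls, samples, "nope", "genic"),
               "no such flag")

  fisher <- clinical_association(calls, samples, "family_history", "genic")
  expect_lt(fisher$p, 0.01)
})

test_that("motif GC comparison is one-sided for lower GC in group A", {
  low <- c("AAAT", "ATAT", "AATT")
  high <- c("CCCG", "GCGC", "CCGG")
  expect_lt(motif_gc_comparison(low, high)$p, 0.05)
  grp <- c("AT", "AAGT", "ACGT", "AGGC", "GCGC")  # GC 0, .25, .5, .75, 1
  same <- motif_gc_comparison(grp, grp)
  expect_equal(same$p, 0.5, tolerance = 0.15)
  expect_error(motif_gc_comparison("AT", high), "at least 2")
})

test_that("rank tests are near-uniform under exchangeable counts", {
  set.seed(77)
  ps <- replicate(60, {
    samples <- toy_samples(30, 5)
    samples$rare_cnv[sample(30, 12)] <- TRUE
    ids <- sample(samples$sample_id[samples$cohort == "case"], 10)
    calls <- do.call(rbind, lapply(ids, function(s) annotated_call(s)))
    subgroup_comparison(calls, samples, "rare_cnv", "genic")$p
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})
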