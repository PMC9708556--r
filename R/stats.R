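#' Statistical parameters
#'
#' @param n_permutations Case-control label permutations for empirical
#'   p-values (default 10000).
#' @param permutation_seed Seed for the permutation stream.
#' @param fdr_cutoff BH false-discovery-rate cutoff for enrichment-map
#'   nodes (default 0.1).
#' @param similarity_threshold Minimum combined set-similarity for an
#'   enrichment-map edge (default 0.2).
#' @param combine_k Weight of the Jaccard coefficient in the combined
#'   similarity \code{k * Jaccard + (1 - k) * overlap} (default 0.5).
#' @param set_size_bounds Inclusive gene-set size bounds for testing
#'   (default 5 to 1000).
#' @param subgroup_test Rank test for clinical subgroup comparisons:
#'   \code{"ranksum"} (default; groups are unpaired) or
#'   \code{"signedrank"} on paired trimmed order statistics.
#' @return An object of class \code{stats_params}.
#' @export
stats_params <- function(n_permutations = 10000L, permutation_seed = 1L,
                         fdr_cutoff = 0.1, similarity_threshold = 0.2,
                         combine_k = 0.5, set_size_bounds = c(5L, 1000L),
                         subgroup_test = c("ranksum", "signedrank")) {
  subgroup_test <- match.arg(subgroup_test)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  if (fdr_cutoff <= 0 || fdr_cutoff >= 1)
    stop("fdr_cutoff must be in (0, 1)", call. = FALSE)
  if (combine_k < 0 || combine_k > 1)
    stop("combine_k must be in [0, 1]", call. = FALSE)
  structure(list(n_permutations = as.integer(n_permutations),
                 permutation_seed = as.integer(permutation_seed),
                 fdr_cutoff = fdr_cutoff,
                 similarity_threshold = similarity_threshold,
                 combine_k = combine_k,
                 set_size_bounds = as.integer(set_size_bounds),
                 subgroup_test = subgroup_test),
            class = "stats_params")
}

# exact Wilcoxon when the data permit (small, tie-free), else normal
# approximation with continuity correction
.wilcox_p <- function(x, y, alternative, paired = FALSE) {
  tie_free <- if (paired) !any(duplicated(abs(x - y))) && all(x != y)
              else !any(duplicated(c(x, y)))
  if (tie_free && length(x) < 30 && length(y) < 30)
    stats::wilcox.test(x, y, alternative = alternative, exact = TRUE,
                       paired = paired)$p.value
  else
    stats::wilcox.test(x, y, alternative = alternative, exact = FALSE,
                       correct = TRUE, paired = paired)$p.value
}

.is_autosomal <- function(contig) !grepl("(chr)?[XY]$", contig)

.select_class <- function(calls, element_class) {
  if (!nrow(calls)) return(logical(0))
  switch(element_class,
         all = rep(TRUE, nrow(calls)),
         exon_proximal = {
           if (is.null(calls$exon_proximal))
             stop("calls are not annotated (no exon_proximal column)",
                  call. = FALSE)
           calls$exon_proximal %in% TRUE
         },
         genic = calls$element_class != "intergenic",
         calls$element_class == element_class)
}

# per-sample counts of rare autosomal calls in a class
.class_counts <- function(calls, sample_ids, element_class) {
  if (nrow(calls)) {
    keep <- .is_autosomal(calls$contig)
    if (!is.null(calls$rare)) keep <- keep & calls$rare %in% TRUE
    calls <- calls[keep, , drop = FALSE]
  }
  sel <- calls[.select_class(calls, element_class), , drop = FALSE]
  cnt <- table(factor(sel$sample_id, levels = sample_ids))
  stats::setNames(as.integer(cnt), sample_ids)
}

# Wald z for the class-count coefficient, with a score-statistic fallback
# when the logistic fit does not converge or separates. X includes an
# intercept in column 1 and the class count in column 2.
.burden_stat <- function(X, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                    control = stats::glm.control(
                                      epsilon = 1e-8, maxit = 100))),
    error = function(e) NULL)
  clean <- !is.null(fit) && fit$converged &&
    all(is.finite(fit$coefficients)) && abs(fit$coefficients[2]) < 15
  if (clean) {
    w <- fit$weights
    XtWX <- crossprod(X, X * w)
    cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (!is.null(cov)) {
      se <- sqrt(cov[2, 2])
      return(list(z = fit$coefficients[2] / se, beta = fit$coefficients[2],
                  se = se, clean = TRUE))
    }
  }
  # score test under the covariate-only null model
  Z <- X[, -2, drop = FALSE]
  nf <- suppressWarnings(stats::glm.fit(Z, y, family = stats::binomial()))
  p <- nf$fitted.values
  w <- p * (1 - p)
  cc <- X[, 2]
  U <- sum((y - p) * cc)
  ZtWZ <- crossprod(Z, Z * w)
  ZtWc <- crossprod(Z, cc * w)
  V <- sum(cc * cc * w) - drop(crossprod(ZtWc, solve(ZtWZ, ZtWc)))
  z <- if (V > 0) U / sqrt(V) else 0
  list(z = z, beta = NA_real_, se = NA_real_, clean = FALSE)
}

.burden_design <- function(calls, samples, element_class,
                           covariates = c("sex", "total")) {
  cc <- samples[samples$cohort %in% c("case", "control"), , drop = FALSE]
  if (!nrow(cc)) stop("no case/control samples", call. = FALSE)
  ids <- cc$sample_id
  count <- .class_counts(calls, ids, element_class)
  y <- as.integer(cc$cohort == "case")
  X <- cbind(`(Intercept)` = 1, count = count)
  if ("sex" %in% covariates) {
    sex <- as.integer(cc$sex == "male")
    if (stats::var(sex) > 0) X <- cbind(X, sex = sex)
  }
  if ("total" %in% covariates && element_class != "all") {
    total <- .class_counts(calls, ids, "all")
    # drop a redundant covariate when the class count IS the total count
    if (stats::var(total) > 0 && stats::var(total - count) > 0)
      X <- cbind(X, total = total)
  }
  list(X = X, y = y, ids = ids, count = count,
       cohort = cc$cohort)
}

#' Case-control burden test for rare expansions
#'
#' Fits a logistic regression of affected status (control = 0, case = 1)
#' on the per-sample count of rare autosomal expansion calls in a
#' functional element class, with biological sex and the total per-sample
#' rare-call count as covariates, and reports the one-sided Wald test for
#' a positive class coefficient (\code{p = 1 - pnorm(z)}: higher burden in
#' cases). With \code{n_permutations > 0} an empirical p-value is computed
#' by permuting affected labels among the retained samples (covariates
#' stay attached to their samples), using the estimator
#' \code{(1 + #(z_perm >= z_obs)) / (1 + B)} which can never be zero.
#'
#' When the fit does not converge or the data separate, the Wald result is
#' suppressed (flagged) and the permutation p, computed from a score
#' statistic, is still valid. When every per-sample class count is equal
#' the test is degenerate: z = 0, p = 0.5, flagged.
#'
#' @param calls Annotated call data frame (rare calls are selected via the
#'   \code{rare} column when present; sex-chromosome calls are dropped).
#' @param samples Sample metadata (reference cohort is excluded
#'   automatically).
#' @param element_class One of the element classes, or
#'   \code{"exon_proximal"}, \code{"genic"}, \code{"intergenic"},
#'   \code{"all"}.
#' @param params A \code{\link{stats_params}} (permutation count and seed).
#' @param n_permutations Number of label permutations (overrides
#'   \code{params}; 0 skips the permutation test).
#' @param covariates Character subset of \code{c("sex", "total")}.
#' @return An object of class \code{tre_burden} with coefficients, odds
#'   ratio, one-sided Wald z and p, empirical p, carrier counts by cohort
#'   and flags; supports \code{print}, \code{summary} and \code{coef}.
#' @export
tre_burden <- function(calls, samples, element_class,
                       params = stats_params(),
                       n_permutations = params$n_permutations,
                       covariates = c("sex", "total")) {
  d <- .burden_design(calls, samples, element_class, covariates)
  degenerate <- stats::var(d$count) == 0
  if (degenerate) {
    st <- list(z = 0, beta = NA_real_, se = NA_real_, clean = FALSE)
  } else {
    st <- .burden_stat(d$X, d$y)
  }
  res <- list(
    element_class = element_class,
    n_cases = sum(d$y), n_controls = sum(1 - d$y),
    n_carriers_case = sum(d$count > 0 & d$y == 1),
    n_carriers_control = sum(d$count > 0 & d$y == 0),
    beta = unname(st$beta), se = unname(st$se),
    odds_ratio = unname(exp(st$beta)),
    wald_z = if (degenerate) 0 else if (st$clean) unname(st$z) else NA_real_,
    wald_p_one_sided = if (degenerate) 0.5
      else if (st$clean) stats::pnorm(unname(st$z), lower.tail = FALSE)
      else NA_real_,
    empirical_p = NA_real_,
    n_permutations = 0L,
    covariates = setdiff(colnames(d$X), c("(Intercept)", "count")),
    flagged = degenerate || !st$clean,
    note = if (degenerate) "degenerate: constant class count"
      else if (!st$clean) "non-convergence or separation: Wald suppressed"
      else ""
  )
  class(res) <- "tre_burden"
  if (n_permutations > 0L && !degenerate) {
    res$empirical_p <- permutation_p(calls, samples, element_class,
                                     params = params,
                                     n_permutations = n_permutations,
                                     covariates = covariates)
    res$n_permutations <- as.integer(n_permutations)
  }
  res
}

#' Permutation empirical p-value for the burden test
#'
#' Permutes affected labels among retained case/control samples
#' \code{n_permutations} times (seeded from
#' \code{params$permutation_seed}); the empirical p is
#' \code{(1 + #(z_perm >= z_obs)) / (1 + B)}. The permuted statistic is the
#' same one used on the observed labels (Wald z, or the score z when the
#' fit is unstable), so the comparison is like-for-like.
#'
#' @inheritParams tre_burden
#' @return Empirical p-value in (0, 1].
#' @export
permutation_p <- function(calls, samples, element_class,
                          params = stats_params(),
                          n_permutations = params$n_permutations,
                          covariates = c("sex", "total")) {
  d <- .burden_design(calls, samples, element_class, covariates)
  if (stats::var(d$count) == 0) return(1)
  z_obs <- .burden_stat(d$X, d$y)$z
  set.seed(params$permutation_seed)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    zb <- .burden_stat(d$X, sample(d$y))$z
    if (zb >= z_obs) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_permutations)
}

#' @export
print.tre_burden <- function(x, ...) {
  cat(sprintf("Rare TRE burden test: %s\n", x$element_class))
  cat(sprintf("  %d cases (%d carriers) vs %d controls (%d carriers)\n",
              x$n_cases, x$n_carriers_case, x$n_controls,
              x$n_carriers_control))
  if (!is.na(x$odds_ratio))
    cat(sprintf("  OR = %.3f (beta = %.3f, SE = %.3f)\n", x$odds_ratio,
                x$beta, x$se))
  if (!is.na(x$wald_z))
    cat(sprintf("  one-sided Wald: z = %.3f, p = %.4g\n", x$wald_z,
                x$wald_p_one_sided))
  if (!is.na(x$empirical_p))
    cat(sprintf("  empirical p (%d permutations) = %.4g\n",
                x$n_permutations, x$empirical_p))
  if (x$flagged) cat("  [flagged] ", x$note, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::summary
summary.tre_burden <- function(object, ...) {
  print(object)
  cat(sprintf("  covariates: %s\n",
              if (length(object$covariates))
                paste(object$covariates, collapse = ", ") else "none"))
  invisible(object)
}

#' @exportS3Method stats::coef
coef.tre_burden <- function(object, ...) {
  c(beta = object$beta, se = object$se, odds_ratio = object$odds_ratio)
}

#' Proportion of cohort samples carrying a rare expansion
#'
#' @param calls Annotated rare calls.
#' @param samples Retained sample metadata.
#' @param element_class Element class (see \code{\link{tre_burden}}).
#' @param cohort Cohort name.
#' @return Proportion in [0, 1] of cohort samples with at least one rare
#'   call of the class.
#' @export
carrier_proportion <- function(calls, samples, element_class, cohort) {
  ids <- samples$sample_id[samples$cohort == cohort]
  if (!length(ids)) stop("empty cohort: ", cohort, call. = FALSE)
  cnt <- .class_counts(calls, ids, element_class)
  mean(cnt > 0)
}

#' Bias-corrected control carrier proportion
#'
#' Scales the raw control carrier proportion by the case/control ratio of
#' intergenic carrier rates, using the intergenic class (where no disease
#' signal is expected) to absorb residual technical imbalance between the
#' cohorts. The scaling factor may be supplied directly instead.
#'
#' @param raw Raw control carrier proportion.
#' @param case_intergenic_rate,control_intergenic_rate Intergenic carrier
#'   rates per cohort.
#' @param factor Optional explicit correction factor (overrides the rates).
#' @return Corrected proportion.
#' @export
bias_corrected_control_proportion <- function(raw,
                                              case_intergenic_rate = NULL,
                                              control_intergenic_rate = NULL,
                                              factor = NULL) {
  if (is.null(factor)) {
    if (is.null(case_intergenic_rate) || is.null(control_intergenic_rate))
      stop("supply either both intergenic rates or an explicit factor",
           call. = FALSE)
    if (control_intergenic_rate <= 0)
      stop("control intergenic rate must be > 0", call. = FALSE)
    factor <- case_intergenic_rate / control_intergenic_rate
  }
  raw * factor
}

#' Attributable risk in percentage points
#'
#' The case carrier proportion minus the (bias-corrected) control carrier
#' proportion, expressed in percentage points: an estimate of the share of
#' disease risk collectively accounted for by the expansion class.
#'
#' @param case_proportion,control_proportion Proportions in [0, 1].
#' @return Difference in percentage points; negative values (control
#'   excess) are returned with a warning.
#' @export
attributable_risk <- function(case_proportion, control_proportion) {
  stopifnot(case_proportion >= 0, case_proportion <= 1,
            control_proportion >= 0, control_proportion <= 1)
  ar <- (case_proportion - control_proportion) * 100
  if (ar < 0)
    warning("control proportion exceeds case proportion: negative risk",
            call. = FALSE)
  ar
}

#' One-sided Fisher enrichment of a gene set
#'
#' Tests over-representation of expansion-associated genes in a gene set
#' against the rest of the universe: a 2x2 table (in set vs not, TRE vs
#' not) with a one-sided hypergeometric p (enrichment direction) and the
#' sample odds ratio (Haldane-Anscombe 0.5 correction only when a cell is
#' zero).
#'
#' @param set Character vector of gene ids (intersected with the universe).
#' @param tre_genes Expansion-associated gene ids.
#' @param universe Background gene universe.
#' @return Data frame row: \code{overlap}, \code{set_size},
#'   \code{odds_ratio}, \code{p_one_sided}.
#' @export
fisher_enrichment <- function(set, tre_genes, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  set <- intersect(unique(set), universe)
  tre_genes <- intersect(unique(tre_genes), universe)
  a <- length(intersect(set, tre_genes))
  b <- length(set) - a
  cc <- length(tre_genes) - a
  d <- length(universe) - a - b - cc
  p <- stats::phyper(a - 1L, length(tre_genes),
                     length(universe) - length(tre_genes), length(set),
                     lower.tail = FALSE)
  cells <- c(a, b, cc, d)
  if (any(cells == 0L)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  data.frame(overlap = a, set_size = length(set), odds_ratio = or,
             p_one_sided = p)
}

.set_similarity <- function(a, b, k) {
  inter <- length(intersect(a, b))
  jac <- inter / length(union(a, b))
  ov <- inter / min(length(a), length(b))
  k * jac + (1 - k) * ov
}

#' Gene-set enrichment suite with enrichment-map output
#'
#' Size-filters the sets (inclusive bounds, after intersection with the
#' universe), runs \code{\link{fisher_enrichment}} on each, corrects the
#' family with Benjamini-Hochberg, and builds enrichment-map node/edge
#' tables: nodes are sets with q at most \code{fdr_cutoff}; edges connect
#' node pairs whose combined similarity (\code{k * Jaccard + (1 - k) *
#' overlap coefficient}) reaches \code{similarity_threshold}.
#'
#' @param sets Named list of gene-id vectors.
#' @param tre_genes Expansion-associated gene ids.
#' @param universe Background gene universe.
#' @param params A \code{\link{stats_params}}.
#' @return List: \code{results} (per tested set: overlap, OR, p, q),
#'   \code{nodes}, \code{edges}.
#' @export
geneset_enrichment_suite <- function(sets, tre_genes, universe,
                                     params = stats_params()) {
  universe <- unique(universe)
  inter <- lapply(sets, function(s) intersect(unique(s), universe))
  sizes <- vapply(inter, length, integer(1))
  ok <- sizes >= params$set_size_bounds[1] & sizes <= params$set_size_bounds[2]
  tested <- inter[ok]
  if (!length(tested))
    stop("no gene set within the size bounds", call. = FALSE)
  res <- do.call(rbind, lapply(names(tested), function(id) {
    r <- fisher_enrichment(tested[[id]], tre_genes, universe)
    cbind(data.frame(set_id = id, stringsAsFactors = FALSE), r)
  }))
  res$q <- stats::p.adjust(res$p_one_sided, method = "BH")
  nodes <- res[res$q <= params$fdr_cutoff, , drop = FALSE]
  edges <- data.frame(set_a = character(), set_b = character(),
                      similarity = numeric(), stringsAsFactors = FALSE)
  if (nrow(nodes) > 1L) {
    ids <- nodes$set_id
    for (i in seq_len(length(ids) - 1L)) for (j in seq(i + 1L, length(ids))) {
      s <- .set_similarity(tested[[ids[i]]], tested[[ids[j]]],
                           params$combine_k)
      if (s >= params$similarity_threshold)
        edges <- rbind(edges, data.frame(set_a = ids[i], set_b = ids[j],
                                         similarity = s,
                                         stringsAsFactors = FALSE))
    }
  }
  rownames(res) <- rownames(nodes) <- NULL
  list(results = res, nodes = nodes, edges = edges)
}

#' Constraint-score shift of expansion-associated genes
#'
#' One-sided Wilcoxon rank-sum test for expansion-associated genes having
#' LOWER constraint scores (more loss-of-function constrained, LOEUF-like)
#' than all other scored genes.
#'
#' @param tre_genes Expansion-associated gene ids.
#' @param constraint Data frame \code{gene_id}, \code{score}.
#' @return List: \code{p}, \code{n_tre}, \code{n_other}, medians.
#' @export
constraint_comparison <- function(tre_genes, constraint) {
  x <- constraint$score[constraint$gene_id %in% tre_genes]
  y <- constraint$score[!constraint$gene_id %in% tre_genes]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 scored genes in each group", call. = FALSE)
  list(p = .wilcox_p(x, y, "less"), n_tre = length(x), n_other = length(y),
       median_tre = stats::median(x), median_other = stats::median(y))
}

.rank_test_p <- function(x, y, alternative, test) {
  if (test == "ranksum") {
    .wilcox_p(x, y, alternative)
  } else {
    k <- min(length(x), length(y))
    xs <- sort(x)[seq_len(k)]; ys <- sort(y)[seq_len(k)]
    if (all(xs == ys)) return(if (alternative == "two.sided") 1 else 0.5)
    .wilcox_p(xs, ys, alternative, paired = TRUE)
  }
}

#' Clinical subgroup burden comparison
#'
#' Among cases, compares per-sample rare-call counts of an element class
#' between samples with and without a clinical flag; one-sided for a
#' higher burden in the flag-present group.
#'
#' @param calls Annotated rare calls.
#' @param samples Sample metadata with the flag column.
#' @param flag Name of a logical clinical column (e.g.
#'   \code{"family_history"}).
#' @param element_class Element class.
#' @param params A \code{\link{stats_params}} (rank-test choice).
#' @return List: \code{p}, group sizes and mean counts.
#' @export
subgroup_comparison <- function(calls, samples, flag, element_class,
                                params = stats_params()) {
  cases <- samples[samples$cohort == "case", , drop = FALSE]
  if (!flag %in% names(cases)) stop("no such flag: ", flag, call. = FALSE)
  fl <- cases[[flag]] %in% TRUE
  if (!any(fl) || all(fl))
    stop("both flag groups must be non-empty among cases", call. = FALSE)
  cnt <- .class_counts(calls, cases$sample_id, element_class)
  x <- cnt[fl]; y <- cnt[!fl]
  list(p = .rank_test_p(x, y, "greater", params$subgroup_test),
       n_present = length(x), n_absent = length(y),
       mean_present = mean(x), mean_absent = mean(y))
}

#' Carrier-by-flag association (count test)
#'
#' One-sided Fisher's exact test of the 2x2 table carrier status (at least
#' one rare call of the class) by clinical flag among cases - the count
#' test alternative to \code{\link{subgroup_comparison}}.
#'
#' @inheritParams subgroup_comparison
#' @return List: \code{p}, \code{odds_ratio}, the 2x2 table.
#' @export
clinical_association <- function(calls, samples, flag, element_class) {
  cases <- samples[samples$cohort == "case", , drop = FALSE]
  if (!flag %in% names(cases)) stop("no such flag: ", flag, call. = FALSE)
  fl <- cases[[flag]] %in% TRUE
  carrier <- .class_counts(calls, cases$sample_id, element_class) > 0
  tab <- table(factor(carrier, levels = c(TRUE, FALSE)),
               factor(fl, levels = c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Motif GC-content comparison
#'
#' One-sided rank-sum test for the motifs of group A (e.g. expanded
#' repeats) having lower GC content than group B (e.g. unexpanded
#' repeats).
#'
#' @param motifs_a,motifs_b Character vectors of motifs (>= 2 each).
#' @return List: \code{p}, mean GC per group.
#' @export
motif_gc_comparison <- function(motifs_a, motifs_b) {
  if (length(motifs_a) < 2L || length(motifs_b) < 2L)
    stop("need at least 2 motifs per group", call. = FALSE)
  ga <- vapply(motifs_a, motif_gc, numeric(1))
  gb <- vapply(motifs_b, motif_gc, numeric(1))
  list(p = .wilcox_p(ga, gb, "less"),
       mean_gc_a = mean(ga), mean_gc_b = mean(gb))
}
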