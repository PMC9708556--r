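#' Quality-control parameters
#'
#' @param locus_filter_alpha Significance level of the cross-cohort locus
#'   bias filter (default 0.05).
#' @param sd_threshold Standard-deviation cutoff for sample outlier
#'   exclusion on Anscombe-transformed counts (default 3).
#' @param locus_filter_test Rank test used by the locus filter:
#'   \code{"ranksum"} (two-sided Mann-Whitney on observed sizes, the
#'   default) or \code{"signedrank"} (signed-rank on paired trimmed order
#'   statistics, for strict replication of the published description; the
#'   cohorts are unpaired, so rank-sum is the statistically appropriate
#'   default).
#' @return An object of class \code{qc_params}.
#' @export
qc_params <- function(locus_filter_alpha = 0.05, sd_threshold = 3,
                      locus_filter_test = c("ranksum", "signedrank")) {
  locus_filter_test <- match.arg(locus_filter_test)
  if (locus_filter_alpha <= 0 || locus_filter_alpha >= 1)
    stop("locus_filter_alpha must be in (0, 1)", call. = FALSE)
  if (sd_threshold <= 0) stop("sd_threshold must be > 0", call. = FALSE)
  structure(list(locus_filter_alpha = locus_filter_alpha,
                 sd_threshold = sd_threshold,
                 locus_filter_test = locus_filter_test),
            class = "qc_params")
}

#' Anscombe variance-stabilizing transform
#'
#' \code{2 * sqrt(x + 3/8)}, applied to per-sample counts before outlier
#' screening to bring the count distribution closer to Gaussian.
#'
#' @param x Non-negative counts.
#' @return Transformed values; strictly increasing in \code{x}.
#' @examples
#' anscombe(0)   # 2 * sqrt(0.375)
#' @export
anscombe <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("counts must be >= 0", call. = FALSE)
  2 * sqrt(x + 3 / 8)
}

.locus_p_value <- function(x, y, test) {
  if (test == "ranksum") {
    .wilcox_p(x, y, "two.sided")
  } else {
    # pair trimmed order statistics; a paired test needs equal lengths
    k <- min(length(x), length(y))
    xs <- sort(x)[seq_len(k)]; ys <- sort(y)[seq_len(k)]
    if (all(xs == ys)) return(1)
    .wilcox_p(xs, ys, "two.sided", paired = TRUE)
  }
}

#' Cross-cohort locus bias filter
#'
#' Removes loci whose observed size distributions differ between the case
#' and control cohorts (two-sided rank test at
#' \code{params$locus_filter_alpha}), guarding the burden analysis against
#' technical batch differences between the two sequencing cohorts. Missing
#' sizes are excluded, not imputed: the filter targets distributional bias
#' among detected signals. Loci observed in only one cohort (or in a single
#' sample) cannot be tested and are retained, flagged untestable. The
#' reference panel plays no role here.
#'
#' @param mat A \code{\link{size_matrix}}.
#' @param samples Sample metadata with \code{sample_id}, \code{cohort}.
#' @param params A \code{\link{qc_params}}.
#' @return List with \code{matrix} (filtered \code{size_matrix}) and
#'   \code{report} (data frame of per-locus p-values and status, an element
#'   of the QC report).
#' @export
filter_batch_loci <- function(mat, samples, params = qc_params()) {
  stopifnot(inherits(mat, "size_matrix"))
  if (nrow(mat$loci) == 0L) stop("empty size matrix", call. = FALSE)
  case_ids <- samples$sample_id[samples$cohort == "case"]
  ctrl_ids <- samples$sample_id[samples$cohort == "control"]
  if (!length(case_ids) || !length(ctrl_ids))
    stop("both case and control cohorts must be present", call. = FALSE)
  case_ids <- intersect(case_ids, mat$samples)
  ctrl_ids <- intersect(ctrl_ids, mat$samples)
  if (!length(case_ids) || !length(ctrl_ids))
    stop("case/control samples absent from the size matrix", call. = FALSE)

  n <- nrow(mat$loci)
  p <- rep(NA_real_, n)
  status <- character(n)
  for (i in seq_len(n)) {
    x <- mat$sizes[i, case_ids]; x <- x[!is.na(x)]
    y <- mat$sizes[i, ctrl_ids]; y <- y[!is.na(y)]
    if (length(x) == 0L || length(y) == 0L || length(x) + length(y) < 3L) {
      status[i] <- "untestable"
      next
    }
    p[i] <- .locus_p_value(x, y, params$locus_filter_test)
    status[i] <- if (!is.na(p[i]) && p[i] < params$locus_filter_alpha)
      "removed" else "retained"
  }
  keep <- status != "removed"
  report <- data.frame(locus_id = mat$loci$locus_id, p_value = p,
                       status = status, stringsAsFactors = FALSE)
  out <- size_matrix(mat$loci[keep, , drop = FALSE], mat$samples,
                     mat$sizes[keep, , drop = FALSE])
  list(matrix = out, report = report)
}

#' Flag per-sample outliers on Anscombe-transformed counts
#'
#' A sample is excluded when its Anscombe-transformed count deviates from
#' the cohort mean by more than \code{sd_threshold} standard deviations on
#' either count axis: the number of detected tandem-repeat loci, or the
#' number of called expansions. When an axis has zero spread no sample is
#' excluded on that axis. Expansion calling should be repeated on the
#' retained samples after exclusion.
#'
#' @param locus_counts Named (by sample id) counts of detected loci.
#' @param tre_counts Named counts of called expansions; may be omitted to
#'   screen on detected loci alone.
#' @param params A \code{\link{qc_params}}.
#' @return Data frame per sample: transformed counts, z-scores per axis,
#'   and \code{excluded}.
#' @export
flag_outlier_samples <- function(locus_counts, tre_counts = NULL,
                                 params = qc_params()) {
  if (length(locus_counts) < 3L)
    stop("need at least 3 samples for outlier screening", call. = FALSE)
  zscore <- function(counts) {
    t <- anscombe(counts)
    s <- stats::sd(t)
    if (is.na(s) || s == 0) rep(0, length(t)) else (t - mean(t)) / s
  }
  z_loci <- zscore(locus_counts)
  z_tre <- if (is.null(tre_counts)) rep(0, length(locus_counts))
           else zscore(tre_counts[names(locus_counts)])
  excluded <- abs(z_loci) > params$sd_threshold |
    abs(z_tre) > params$sd_threshold
  data.frame(sample_id = names(locus_counts),
             locus_count = as.vector(locus_counts),
             tre_count = if (is.null(tre_counts)) NA_integer_
                         else as.vector(tre_counts[names(locus_counts)]),
             z_locus = z_loci, z_tre = z_tre, excluded = excluded,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample detected-locus counts
#'
#' @param mat A \code{\link{size_matrix}}.
#' @return Named integer vector: number of loci with observed signal per
#'   sample.
#' @export
count_detected_loci <- function(mat) {
  stopifnot(inherits(mat, "size_matrix"))
  ct <- colSums(!is.na(mat$sizes))
  storage.mode(ct) <- "integer"
  ct
}

#' Spearman concordance between two size estimates
#'
#' Used to check agreement between the profile-based size estimates and an
#' orthogonal genotyper's sizes at the same loci. Monotone agreement gives
#' rho = 1 regardless of scale.
#'
#' @param x,y Equal-length size vectors (pairwise complete, length >= 3).
#' @return List with \code{rho}, \code{p} (two-sided) and \code{flagged}
#'   (TRUE when rho is undefined because a vector is constant).
#' @export
size_concordance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, flagged = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, flagged = FALSE)
}

#' Full sample and locus quality control
#'
#' Pipeline-order QC: (1) the cross-cohort locus bias filter, then (2)
#' sample outlier exclusion on detected-locus and called-expansion counts
#' (calling is run once on the filtered matrix to obtain the second axis),
#' after which expansion calling should be repeated on the retained set.
#'
#' @param mat A \code{\link{size_matrix}}.
#' @param samples Sample metadata.
#' @param params A \code{\link{qc_params}}.
#' @param caller A \code{\link{caller_params}} used for the provisional
#'   call pass that feeds the TRE-count axis.
#' @return An object of class \code{qc_report}: filtered matrix, retained
#'   sample metadata, locus report, sample report, and input/retained
#'   counts for both axes.
#' @export
run_qc <- function(mat, samples, params = qc_params(),
                   caller = caller_params()) {
  lf <- filter_batch_loci(mat, samples, params)
  qc_cohort <- samples$sample_id[samples$cohort %in% c("case", "control")]
  qc_cohort <- intersect(qc_cohort, mat$samples)

  loci_counts <- count_detected_loci(lf$matrix)[qc_cohort]
  prelim <- call_expansions(lf$matrix, caller)
  tre_counts <- table(factor(prelim$sample_id, levels = qc_cohort))
  tre_counts <- stats::setNames(as.integer(tre_counts), qc_cohort)

  sample_report <- flag_outlier_samples(loci_counts, tre_counts, params)
  keep_ids <- c(setdiff(mat$samples, qc_cohort),
                sample_report$sample_id[!sample_report$excluded])
  keep <- mat$samples %in% keep_ids
  out_mat <- size_matrix(lf$matrix$loci, lf$matrix$samples[keep],
                         lf$matrix$sizes[, keep, drop = FALSE])
  out <- list(
    matrix = out_mat,
    samples = samples[samples$sample_id %in% keep_ids, , drop = FALSE],
    locus_report = lf$report,
    sample_report = sample_report,
    n_loci_input = nrow(mat$loci), n_loci_retained = nrow(out_mat$loci),
    n_samples_input = length(qc_cohort),
    n_samples_retained = sum(!sample_report$excluded)
  )
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("TRE quality control\n")
  cat(sprintf("  loci: %d -> %d (%d removed as cross-cohort biased, %d untestable)\n",
              x$n_loci_input, x$n_loci_retained,
              sum(x$locus_report$status == "removed"),
              sum(x$locus_report$status == "untestable")))
  cat(sprintf("  case/control samples: %d -> %d (%d excluded as outliers)\n",
              x$n_samples_input, x$n_samples_retained,
              sum(x$sample_report$excluded)))
  invisible(x)
}
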