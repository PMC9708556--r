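#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration object describing a synthetic
#' case/control/reference study: cohort sizes, a toy genome, per-locus
#' repeat-size baselines, planted rare expansions, cohort-specific batch
#' shifts, and globally inflated outlier samples. The defaults describe the
#' standard simulated study used throughout the package: 250 cases, 225
#' controls and a 2504-sample reference panel typed at 1000 repeat loci,
#' with 20 planted rare expansion loci of which 8 are exon-proximal and
#' together carry 13 case carriers.
#'
#' Repeat-size semantics follow depth-normalized anchored in-repeat read
#' counts: a locus only produces a signal for a sample when the repeat tract
#' exceeds the read length, so non-carriers are missing at a locus except
#' with probability \code{background_detect_rate}. Carrier sizes are the
#' locus baseline times \code{multiplier}. A small cohort-exchangeable
#' "null expansion" rate plants real expansions equally in all cohorts so
#' that the population carries rare expansions unrelated to case status.
#'
#' @param n_cases,n_controls,n_reference Cohort sizes.
#' @param n_loci Number of repeat loci.
#' @param n_genes Number of genes in the toy genome.
#' @param exons_per_gene Integer range (length 2) of exon counts per gene.
#' @param read_length Read length in bp; repeat tracts must exceed this to
#'   be detected (detection is simulated via \code{background_detect_rate}).
#' @param motif_length_range Allowed motif lengths in bp (within 2-20).
#' @param mean_depth,depth_sd Per-sample sequencing depth distribution
#'   (normal, truncated at 10x).
#' @param background_detect_rate Probability that a non-carrier shows any
#'   signal at a locus.
#' @param baseline_median Median normalized size across loci.
#' @param baseline_spread Across-locus sdlog of the lognormal baseline.
#' @param size_noise Within-locus sdlog of background (non-carrier) sizes.
#' @param carrier_noise Within-locus sdlog of carrier sizes.
#' @param null_expansion_rate Per sample-locus probability of a
#'   cohort-exchangeable expansion (same size law as planted carriers).
#' @param null_exon_proximal_factor Multiplier on
#'   \code{null_expansion_rate} at exon-proximal loci (exon, UTR, or
#'   intron within the junction window), emulating the constraint-driven
#'   depletion of population expansions near coding sequence (default
#'   0.1).
#' @param planted Data frame of planted expansion loci with columns
#'   \code{element_class}, \code{n_case}, \code{n_control},
#'   \code{n_reference}, \code{multiplier} (see
#'   \code{\link{default_planted_loci}}), or the strings
#'   \code{"default"} / \code{"none"}.
#' @param batch_loci_fraction Fraction of loci given a cohort-specific
#'   multiplicative size shift (a technical batch artifact).
#' @param batch_shift Multiplicative shift applied at batch loci.
#' @param batch_cohort Which cohort receives the batch shift.
#' @param outlier_sample_count Number of case/control samples with globally
#'   inflated detected-locus counts.
#' @param outlier_detect_multiplier Detection-rate inflation for outlier
#'   samples.
#' @param contig_length Optional fixed contig length in bp; by default
#'   contigs are sized to fit the requested genes. An explicit length too
#'   small to place the genes is an error at generation time.
#' @param seed Integer seed; identical configurations (including the seed)
#'   regenerate byte-identical outputs.
#' @return An object of class \code{sim_config} (a validated list).
#' @seealso \code{\link{simulate_annotation}}, \code{\link{simulate_cohort}},
#'   \code{\link{simulate_gene_resources}}
#' @export
sim_config <- function(n_cases = 250L,
                       n_controls = 225L,
                       n_reference = 2504L,
                       n_loci = 1000L,
                       n_genes = 60L,
                       exons_per_gene = c(2L, 5L),
                       read_length = 150L,
                       motif_length_range = c(2L, 20L),
                       mean_depth = 30,
                       depth_sd = 5,
                       background_detect_rate = 0.2,
                       baseline_median = 2,
                       baseline_spread = 0.3,
                       size_noise = 0.2,
                       carrier_noise = 0.15,
                       null_expansion_rate = 5e-4,
                       null_exon_proximal_factor = 0.1,
                       planted = default_planted_loci(),
                       batch_loci_fraction = 0.02,
                       batch_shift = 1.5,
                       batch_cohort = c("case", "control"),
                       outlier_sample_count = 2L,
                       outlier_detect_multiplier = 3,
                       contig_length = NULL,
                       seed = 1L) {
  batch_cohort <- match.arg(batch_cohort)
  if (is.character(planted))  # YAML-friendly shortcuts
    planted <- switch(planted,
                      none = default_planted_loci()[0, ],
                      default = default_planted_loci(),
                      stop("planted must be a data frame, 'default' or 'none'",
                           call. = FALSE))
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_reference = as.integer(n_reference), n_loci = as.integer(n_loci),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    read_length = as.integer(read_length),
    motif_length_range = as.integer(motif_length_range),
    mean_depth = mean_depth, depth_sd = depth_sd,
    background_detect_rate = background_detect_rate,
    baseline_median = baseline_median, baseline_spread = baseline_spread,
    size_noise = size_noise, carrier_noise = carrier_noise,
    null_expansion_rate = null_expansion_rate,
    null_exon_proximal_factor = null_exon_proximal_factor,
    planted = planted,
    batch_loci_fraction = batch_loci_fraction, batch_shift = batch_shift,
    batch_cohort = batch_cohort,
    outlier_sample_count = as.integer(outlier_sample_count),
    outlier_detect_multiplier = outlier_detect_multiplier,
    contig_length = if (is.null(contig_length)) NULL else as.integer(contig_length),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default planted-expansion layout
#'
#' 20 planted rare-expansion loci: 8 exon-proximal intronic loci carrying 13
#' case carriers and no planted control carriers (the exon-proximal
#' case-enrichment signal; control exon-proximal carriers arise only from
#' the background exchangeable rate), plus 12 further loci spread over the
#' other element classes, case/control-balanced in the non-exon-proximal
#' classes.
#'
#' @return Data frame with columns \code{element_class}, \code{n_case},
#'   \code{n_control}, \code{n_reference}, \code{multiplier}.
#' @export
default_planted_loci <- function() {
  data.frame(
    element_class = c(rep("intron_proximal", 8L),
                      rep("intron_distal", 4L),
                      rep("intergenic", 2L),
                      rep("upstream", 2L),
                      "downstream", "utr5", "utr3", "exon"),
    n_case = c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L,
               1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    n_control = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
                  1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L),
    n_reference = c(1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L,
                    1L, 1L, 0L, 0L, 2L, 2L, 1L, 1L, 1L, 0L, 0L, 0L),
    multiplier = rep(5, 20L),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(cfg$n_cases, cfg$n_controls, cfg$n_reference, cfg$n_loci,
              cfg$n_genes, cfg$outlier_sample_count)
  if (any(counts < 0L)) stop("all counts must be >= 0", call. = FALSE)
  if (cfg$n_loci < 1L) stop("n_loci must be > 0", call. = FALSE)
  mlr <- cfg$motif_length_range
  if (length(mlr) != 2L || mlr[1] > mlr[2] || mlr[1] < 2L || mlr[2] > 20L)
    stop("motif_length_range must lie within 2-20 bp", call. = FALSE)
  probs <- c(cfg$background_detect_rate, cfg$null_expansion_rate,
             cfg$null_exon_proximal_factor, cfg$batch_loci_fraction)
  if (any(probs < 0 | probs > 1))
    stop("rates/fractions must be probabilities in [0, 1]", call. = FALSE)
  p <- cfg$planted
  if (nrow(p)) {
    need <- c("element_class", "n_case", "n_control", "n_reference", "multiplier")
    if (!all(need %in% names(p)))
      stop("planted table must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(p$n_case > cfg$n_cases) || any(p$n_control > cfg$n_controls) ||
        any(p$n_reference > cfg$n_reference))
      stop("planted carrier count exceeds cohort size", call. = FALSE)
    if (any(p$multiplier <= 1))
      stop("planted multiplier must exceed 1", call. = FALSE)
  }
  if (cfg$outlier_sample_count > cfg$n_cases + cfg$n_controls)
    stop("outlier_sample_count exceeds case+control cohort size", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic TRE cohort configuration\n")
  cat(sprintf("  samples: %d cases / %d controls / %d reference\n",
              x$n_cases, x$n_controls, x$n_reference))
  cat(sprintf("  loci: %d over %d genes; %d planted expansion loci\n",
              x$n_loci, x$n_genes, nrow(x$planted)))
  cat(sprintf("  batch loci: %.1f%% (x%.2f on %s cohort); outlier samples: %d\n",
              100 * x$batch_loci_fraction, x$batch_shift, x$batch_cohort,
              x$outlier_sample_count))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
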