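.config_sections <- c("simulate", "qc", "caller", "annotate", "stats")

.known_keys <- function(section) {
  ctor <- switch(section, simulate = sim_config, qc = qc_params,
                 caller = caller_params, annotate = annotation_params,
                 stats = stats_params)
  names(formals(ctor))
}

.validate_config <- function(config) {
  known_top <- c("seed", "out_dir", .config_sections)
  unknown <- setdiff(names(config), known_top)
  if (length(unknown))
    stop("unknown config key '", unknown[1], "'", call. = FALSE)
  for (sec in intersect(.config_sections, names(config))) {
    bad <- setdiff(names(config[[sec]]), .known_keys(sec))
    if (length(bad))
      stop("unknown config key '", sec, ".", bad[1], "'", call. = FALSE)
  }
  invisible(config)
}

.stage_log <- function(stage, msg)
  message(sprintf("[%s] %s", stage, msg))

#' Run the full discovery and burden pipeline
#'
#' Orchestrates simulate -> QC -> call -> annotate -> burden -> enrich ->
#' report on a synthetic study, writing every stage output as plain
#' TSV/BED/JSON under \code{out_dir} plus a machine-readable run manifest
#' (parameters, seeds, and md5 digests of every output). Stage order
#' follows the analysis logic: the locus bias filter and sample QC come
#' first, rare-expansion identification is then performed on the retained
#' set, and burden/enrichment statistics close.
#'
#' @param config Configuration: a named list with optional sections
#'   \code{simulate}, \code{qc}, \code{caller}, \code{annotate},
#'   \code{stats} (arguments to the respective parameter constructors) and
#'   a top-level \code{seed}; or the path to a YAML file with the same
#'   structure. Unknown keys are rejected by name.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the run manifest and the main in-memory
#'   results (qc report, rare calls, regions, burden fits).
#' @export
run_tre_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  .validate_config(config)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim_args <- config$simulate %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  scfg <- do.call(sim_config, sim_args)
  qp <- do.call(qc_params, config$qc %||% list())
  cp <- do.call(caller_params, config$caller %||% list())
  ap <- do.call(annotation_params, config$annotate %||% list())
  stp_args <- config$stats %||% list()
  if (is.null(stp_args$permutation_seed)) stp_args$permutation_seed <- seed
  stp <- do.call(stats_params, stp_args)

  manifest <- list(
    tool = "treburden",
    version = as.character(utils::packageVersion("treburden")),
    seed = seed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(simulate = unclass(scfg)[setdiff(names(unclass(scfg)), "planted")],
                      qc = unclass(qp), caller = unclass(cp),
                      annotate = unclass(ap), stats = unclass(stp)),
    outputs = list()
  )

  # ---- simulate ----
  .stage_log("simulate", sprintf("generating cohort (seed %d)", seed))
  sim_dir <- file.path(out_dir, "simulate")
  paths <- simulate_to_dir(scfg, sim_dir)
  models <- simulate_annotation(scfg)
  cohort <- simulate_cohort(scfg, models)
  resources <- simulate_gene_resources(scfg, models)

  # ---- qc ----
  .stage_log("qc", "locus bias filter and sample outlier screening")
  qc_dir <- file.path(out_dir, "qc"); dir.create(qc_dir, showWarnings = FALSE)
  qc <- run_qc(cohort$matrix, cohort$samples, qp, cp)
  utils::write.table(qc$locus_report, file.path(qc_dir, "locus_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qc$sample_report, file.path(qc_dir, "sample_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_loci_input = qc$n_loci_input, n_loci_retained = qc$n_loci_retained,
         n_samples_input = qc$n_samples_input,
         n_samples_retained = qc$n_samples_retained,
         excluded_samples = qc$sample_report$sample_id[qc$sample_report$excluded]),
    file.path(qc_dir, "qc_summary.json"), auto_unbox = TRUE, pretty = TRUE)

  # ---- call (re-identification on the retained set) ----
  .stage_log("call", "per-locus DBSCAN outlier calling + frequency filter")
  call_dir <- file.path(out_dir, "call"); dir.create(call_dir, showWarnings = FALSE)
  calls <- call_expansions(qc$matrix, cp, qc$samples)
  calls <- population_frequency(calls, qc$samples, cp$freq_cutoff)
  rare <- calls[calls$rare, , drop = FALSE]
  regions <- merge_regions(rare, cp$merge_distance)
  utils::write.table(regions, file.path(call_dir, "regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # ---- annotate ----
  .stage_log("annotate", "functional element assignment")
  ann_dir <- file.path(out_dir, "annotate"); dir.create(ann_dir, showWarnings = FALSE)
  elements <- partition_elements(models, ap)
  rare <- annotate_calls(rare, elements, ap, models)
  write_calls(rare, file.path(call_dir, "rare_calls.tsv"))
  write_bed(data.frame(contig = elements$contig, start = elements$start,
                       end = elements$end, name = elements$element_class),
            file.path(ann_dir, "elements.bed"))

  # ---- burden ----
  .stage_log("burden", sprintf("logistic burden tests (%d permutations)",
                               stp$n_permutations))
  burden_dir <- file.path(out_dir, "burden"); dir.create(burden_dir, showWarnings = FALSE)
  classes <- c("exon_proximal", "genic", "intergenic", "intron", "upstream",
               "downstream", "all")
  fits <- lapply(classes, function(cl)
    tre_burden(rare, qc$samples, cl, params = stp))
  names(fits) <- classes
  burden_tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(element_class = f$element_class, n_carriers_case = f$n_carriers_case,
               n_carriers_control = f$n_carriers_control,
               odds_ratio = f$odds_ratio, wald_z = f$wald_z,
               wald_p_one_sided = f$wald_p_one_sided,
               empirical_p = f$empirical_p, flagged = f$flagged)))
  utils::write.table(burden_tab, file.path(burden_dir, "burden.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- enrich ----
  .stage_log("enrich", "gene-set / constraint / GWAS-overlap enrichment")
  enr_dir <- file.path(out_dir, "enrich"); dir.create(enr_dir, showWarnings = FALSE)
  tre_genes <- unique(rare$gene_id[!is.na(rare$gene_id)])
  enr <- tryCatch(
    geneset_enrichment_suite(resources$gene_sets, tre_genes,
                             resources$universe, stp),
    error = function(e) NULL)
  if (!is.null(enr)) {
    utils::write.table(enr$results, file.path(enr_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr$nodes, file.path(enr_dir, "nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr$edges, file.path(enr_dir, "edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  gwas <- fisher_enrichment(resources$gwas_genes, tre_genes,
                            resources$universe)
  constr <- if (length(tre_genes) >= 2L)
    constraint_comparison(tre_genes, resources$constraint) else NULL
  jsonlite::write_json(
    list(gwas_overlap = gwas,
         constraint_p = if (is.null(constr)) NA else constr$p),
    file.path(enr_dir, "overlap_tests.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)

  # ---- manifest + report ----
  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  digests <- tools::md5sum(outputs)
  manifest$outputs <- as.list(stats::setNames(unname(digests),
                                              sub(paste0("^", out_dir, "/?"), "",
                                                  outputs)))
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeline_report(out_dir)

  invisible(list(manifest = manifest, qc = qc, rare_calls = rare,
                 regions = regions, burden = fits, truth = cohort$truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a completed pipeline run
#'
#' Tabulates the run's headline numbers (samples and loci retained, rare
#' expansion calls, distinct regions, carriers and burden statistics per
#' element class, carrier proportions and attributable risk) into
#' \code{report.tsv} and a human-readable \code{report.txt}. Re-running on
#' the same directory reproduces byte-identical reports.
#'
#' @param run_dir Directory written by \code{\link{run_tre_pipeline}}.
#' @return Invisibly, the summary data frame.
#' @export
pipeline_report <- function(run_dir) {
  need <- c(qc = "qc/qc_summary.json", calls = "call/rare_calls.tsv",
            regions = "call/regions.tsv", burden = "burden/burden.tsv",
            samples = "simulate/samples.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run; missing stage outputs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  qc <- jsonlite::read_json(file.path(run_dir, need[["qc"]]),
                            simplifyVector = TRUE)
  rare <- read_calls(file.path(run_dir, need[["calls"]]))
  regions <- utils::read.delim(file.path(run_dir, need[["regions"]]))
  burden <- utils::read.delim(file.path(run_dir, need[["burden"]]))
  samples <- read_samples(file.path(run_dir, need[["samples"]]))
  excluded <- unlist(qc$excluded_samples)
  retained <- samples[!samples$sample_id %in% excluded, , drop = FALSE]

  n_rare <- nrow(unique(rare[, c("sample_id", "locus_id")]))
  prop <- function(class, cohort) {
    if (!nrow(rare)) return(0)
    carrier_proportion(rare, retained, class, cohort)
  }
  case_ep <- prop("exon_proximal", "case")
  ctrl_ep <- prop("exon_proximal", "control")
  case_ig <- prop("intergenic", "case")
  ctrl_ig <- prop("intergenic", "control")
  corrected <- if (ctrl_ig > 0)
    bias_corrected_control_proportion(ctrl_ep, case_ig, ctrl_ig) else ctrl_ep
  ar <- (case_ep - min(corrected, 1)) * 100

  summary <- data.frame(
    metric = c("samples_retained", "loci_retained", "rare_tres",
               "distinct_regions", "case_carrier_prop_exon_proximal",
               "control_carrier_prop_exon_proximal_corrected",
               "attributable_risk_pct"),
    value = c(nrow(retained[retained$cohort != "reference", ]),
              qc$n_loci_retained, n_rare, nrow(regions),
              round(case_ep, 6), round(corrected, 6), round(ar, 4))
  )
  utils::write.table(summary, file.path(run_dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  txt <- c(
    "Rare tandem repeat expansion analysis - run summary",
    sprintf("  case/control samples retained: %d (of %d)",
            nrow(retained[retained$cohort != "reference", ]),
            sum(samples$cohort != "reference")),
    sprintf("  loci retained after bias filter: %s", qc$n_loci_retained),
    sprintf("  rare TREs: %d in %d distinct regions", n_rare, nrow(regions)),
    sprintf("  exon-proximal carrier proportion: cases %.2f%%, controls (corrected) %.2f%%",
            100 * case_ep, 100 * corrected),
    sprintf("  attributable risk: %.2f percentage points", ar),
    "",
    "Burden tests (one-sided, higher burden in cases):",
    sprintf("  %-15s OR = %-8s Wald p = %-10s empirical p = %s",
            burden$element_class,
            ifelse(is.na(burden$odds_ratio), "NA",
                   sprintf("%.3f", burden$odds_ratio)),
            ifelse(is.na(burden$wald_p_one_sided), "NA",
                   sprintf("%.3g", burden$wald_p_one_sided)),
            ifelse(is.na(burden$empirical_p), "NA",
                   sprintf("%.3g", burden$empirical_p)))
  )
  writeLines(txt, file.path(run_dir, "report.txt"))
  invisible(summary)
}
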