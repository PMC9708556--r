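#' Generate a toy genome annotation
#'
#' Lays out non-overlapping gene models on a small number of contigs so that
#' every functional element class (upstream, 5'UTR, exon, core splice site,
#' intron, 3'UTR, downstream, intergenic) exists by construction. Genes
#' alternate between two contigs and between strands; each gene has a single
#' transcript with 5'/3' UTRs occupying the outer ends of the terminal
#' exons.
#'
#' RNG stream: \code{config$seed + 1L}, so the annotation can be regenerated
#' independently of the cohort.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{gene_models} object (see \code{\link{read_gene_models}}).
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  if (config$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (config$exons_per_gene[1] < 2L)
    stop("genes need at least 2 exons so that introns exist", call. = FALSE)
  set.seed(config$seed + 1L)

  utr5_len <- 200L; utr3_len <- 250L; gap <- 4000L
  contigs <- c("chr1", "chr2")
  cursor <- stats::setNames(rep(gap, length(contigs)), contigs)

  genes <- list(); exons <- list(); cds <- list(); utr5 <- list(); utr3 <- list()
  for (g in seq_len(config$n_genes)) {
    ctg <- contigs[(g - 1L) %% length(contigs) + 1L]
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    k <- config$exons_per_gene[1] +
      sample.int(config$exons_per_gene[2] - config$exons_per_gene[1] + 1L,
                 1L) - 1L
    exon_len <- sample(300:400, k, replace = TRUE)
    intron_len <- sample(1500:3000, k - 1L, replace = TRUE)
    gid <- sprintf("g%03d", g)

    gs <- cursor[[ctg]]
    es <- integer(k); ee <- integer(k)
    pos <- gs
    for (i in seq_len(k)) {
      es[i] <- pos; ee[i] <- pos + exon_len[i]
      pos <- ee[i] + if (i < k) intron_len[i] else 0L
    }
    ge <- ee[k]
    cursor[[ctg]] <- ge + gap

    # UTRs occupy the transcript ends of the terminal exons (strand-aware)
    if (strand == "+") {
      u5 <- c(es[1], es[1] + utr5_len)
      u3 <- c(ee[k] - utr3_len, ee[k])
    } else {
      u5 <- c(ee[k] - utr5_len, ee[k])
      u3 <- c(es[1], es[1] + utr3_len)
    }
    # CDS = exons minus both UTR intervals (general interval subtraction)
    pieces <- list()
    for (j in seq_len(k)) {
      segs <- data.frame(start = es[j], end = ee[j])
      for (u in list(u5, u3)) {
        kept <- list()
        for (r in seq_len(nrow(segs))) {
          s <- segs$start[r]; e <- segs$end[r]
          if (e <= u[1] || s >= u[2]) { kept[[length(kept) + 1L]] <- c(s, e); next }
          if (s < u[1]) kept[[length(kept) + 1L]] <- c(s, u[1])
          if (e > u[2]) kept[[length(kept) + 1L]] <- c(u[2], e)
        }
        segs <- if (length(kept))
          as.data.frame(do.call(rbind, kept)) else segs[0, ]
        names(segs) <- c("start", "end")
      }
      if (nrow(segs)) pieces[[length(pieces) + 1L]] <- segs
    }
    cds_iv <- if (length(pieces)) {
      x <- do.call(rbind, pieces)
      data.frame(gene_id = gid, start = x$start, end = x$end)
    } else data.frame(gene_id = character(), start = integer(),
                      end = integer())

    genes[[g]] <- data.frame(gene_id = gid, contig = ctg, strand = strand,
                             start = gs, end = ge)
    exons[[g]] <- data.frame(gene_id = gid, start = es, end = ee)
    cds[[g]] <- cds_iv
    utr5[[g]] <- data.frame(gene_id = gid, start = u5[1], end = u5[2])
    utr3[[g]] <- data.frame(gene_id = gid, start = u3[1], end = u3[2])
  }

  contig_len <- cursor
  if (!is.null(config$contig_length)) {
    if (any(cursor > config$contig_length))
      stop(sprintf(
        "contig too small to place requested genes: need %d bp, have %d",
        max(cursor), config$contig_length), call. = FALSE)
    contig_len[] <- config$contig_length
  }

  models <- list(
    genes = do.call(rbind, genes),
    exons = do.call(rbind, exons),
    cds = do.call(rbind, cds),
    utr5 = do.call(rbind, utr5),
    utr3 = do.call(rbind, utr3),
    contigs = data.frame(contig = contigs,
                         length = as.integer(contig_len[contigs]))
  )
  class(models) <- "gene_models"
  validate_gene_models(models)
  models
}

# Placement categories used by the generator; mapped to annotator vocabulary
# in the emitted truth table.
.locus_categories <- c("exon", "intron_proximal", "intron_distal", "utr5",
                       "utr3", "upstream", "downstream", "intergenic")
.category_probs <- c(exon = 0.05, intron_proximal = 0.20, intron_distal = 0.25,
                     utr5 = 0.05, utr3 = 0.05, upstream = 0.05,
                     downstream = 0.05, intergenic = 0.30)

.category_to_class <- function(cat) {
  cls <- c(exon = "exon", intron_proximal = "intron", intron_distal = "intron",
           utr5 = "utr5", utr3 = "utr3", upstream = "upstream",
           downstream = "downstream", intergenic = "intergenic")
  unname(cls[cat])
}

# Candidate placement slots (start ranges) per category, from gene models.
.placement_slots <- function(models, locus_len, flank = 1000L) {
  g <- models$genes
  slot <- function(contig, lo, hi, gene_id)
    data.frame(contig = contig, lo = lo, hi = hi, gene_id = gene_id,
               stringsAsFactors = FALSE)
  out <- list()
  iv_slots <- function(df, margin = 0L) {
    df <- merge(df, g[, c("gene_id", "contig")], by = "gene_id")
    lo <- df$start + margin; hi <- df$end - locus_len - margin
    ok <- hi >= lo
    slot(df$contig[ok], lo[ok], hi[ok], df$gene_id[ok])
  }
  out$exon <- iv_slots(models$cds)
  out$utr5 <- iv_slots(models$utr5)
  out$utr3 <- iv_slots(models$utr3)

  # introns: gaps between consecutive exons of a gene
  introns <- do.call(rbind, lapply(split(models$exons, models$exons$gene_id),
    function(e) {
      e <- e[order(e$start), ]
      if (nrow(e) < 2L) return(NULL)
      data.frame(gene_id = e$gene_id[1], start = e$end[-nrow(e)],
                 end = e$start[-1])
    }))
  rownames(introns) <- NULL
  intr <- merge(introns, g[, c("gene_id", "contig")], by = "gene_id")
  # proximal: within 10..200 bp of a junction (well inside the 300 bp window)
  prox <- rbind(
    slot(intr$contig, intr$start + 10L, intr$start + 200L, intr$gene_id),
    slot(intr$contig, intr$end - 200L - locus_len,
         intr$end - 10L - locus_len, intr$gene_id))
  out$intron_proximal <- prox[prox$hi >= prox$lo, ]
  dist <- slot(intr$contig, intr$start + 400L, intr$end - 400L - locus_len,
               intr$gene_id)
  out$intron_distal <- dist[dist$hi >= dist$lo, ]

  tss_plus <- g$strand == "+"
  up_lo <- ifelse(tss_plus, g$start - flank, g$end)
  dn_lo <- ifelse(tss_plus, g$end, g$start - flank)
  out$upstream <- slot(g$contig, up_lo + 10L, up_lo + flank - locus_len - 10L,
                       g$gene_id)
  out$downstream <- slot(g$contig, dn_lo + 10L, dn_lo + flank - locus_len - 10L,
                         g$gene_id)

  # intergenic: complement of gene bodies +/- flank, with margin
  inter <- list()
  for (ctg in models$contigs$contig) {
    gi <- g[g$contig == ctg, ]
    blocks <- cbind(gi$start - flank, gi$end + flank)
    blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
    len <- models$contigs$length[models$contigs$contig == ctg]
    prev <- 0L
    for (b in seq_len(nrow(blocks) + 1L)) {
      hi <- if (b <= nrow(blocks)) blocks[b, 1] else len
      if (hi - prev > locus_len + 100L)
        inter[[length(inter) + 1L]] <-
          slot(ctg, prev + 50L, hi - locus_len - 50L, NA_character_)
      if (b <= nrow(blocks)) prev <- max(prev, blocks[b, 2])
    }
  }
  out$intergenic <- do.call(rbind, inter)
  out
}

.random_motif <- function(len, at_rich = FALSE) {
  p <- if (at_rich) c(0.4, 0.1, 0.1, 0.4) else rep(0.25, 4)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate a synthetic cohort of repeat-size profiles
#'
#' Emits a locus x sample matrix of depth-normalized repeat-size estimates
#' with the sparsity structure of anchored in-repeat read profiling: a
#' non-carrier shows signal at a locus only with probability
#' \code{background_detect_rate} (the repeat tract is otherwise shorter than
#' the read length and produces nothing); background sizes are lognormal
#' around a locus-specific baseline; carriers (planted, case-enriched, and
#' cohort-exchangeable "null" expansions) are the baseline times the
#' expansion multiplier. Batch loci get a multiplicative shift in one
#' cohort; outlier samples detect loci at an inflated rate. Internally the
#' generator scales true sizes by each sample's depth and normalizes back,
#' so emitted sizes are invariant to depth rescaling.
#'
#' RNG stream: \code{config$seed + 2L}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param models Gene models from \code{\link{simulate_annotation}}.
#' @return List with components \code{matrix} (a \code{size_matrix}),
#'   \code{samples} (sample metadata data frame) and \code{truth} (a
#'   \code{truth_table} recording carriers, locus element labels, batch loci
#'   and outlier samples).
#' @export
simulate_cohort <- function(config, models) {
  validate_sim_config(config)
  stopifnot(inherits(models, "gene_models"))
  set.seed(config$seed + 2L)
  locus_len <- 50L

  n_s <- config$n_cases + config$n_controls + config$n_reference
  sample_id <- c(sprintf("case%03d", seq_len(config$n_cases)),
                 sprintf("ctrl%03d", seq_len(config$n_controls)),
                 sprintf("ref%04d", seq_len(config$n_reference)))
  cohort <- rep(c("case", "control", "reference"),
                c(config$n_cases, config$n_controls, config$n_reference))
  sex <- sample(c("male", "female"), n_s, replace = TRUE)
  flag <- function(p) cohort == "case" & stats::runif(n_s) < p
  samples <- data.frame(
    sample_id = sample_id, cohort = cohort, sex = sex,
    family_history = flag(0.20),
    intellectual_disability = flag(0.15),
    syndromic_features = flag(0.15),
    early_onset = flag(0.20),
    clinically_relevant_variant = flag(0.13),
    rare_cnv = flag(0.10),
    family_id = NA_character_,
    stringsAsFactors = FALSE
  )
  depth <- pmax(10, stats::rnorm(n_s, config$mean_depth, config$depth_sd))

  # ---- locus placement ----
  slots <- .placement_slots(models, locus_len)
  category <- sample(.locus_categories, config$n_loci, replace = TRUE,
                     prob = .category_probs[.locus_categories])
  placed <- lapply(stats::setNames(nm = models$contigs$contig),
                   function(x) data.frame(start = integer(), end = integer()))
  loci <- data.frame(contig = character(config$n_loci),
                     start = integer(config$n_loci),
                     end = integer(config$n_loci),
                     motif = character(config$n_loci),
                     category = category,
                     gene_id = NA_character_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(config$n_loci)) {
    sl <- slots[[category[i]]]
    if (is.null(sl) || nrow(sl) == 0L)
      stop("no placement slots for locus category '", category[i],
           "': genome too small", call. = FALSE)
    ok <- FALSE
    for (try in seq_len(60L)) {
      r <- sl[sample.int(nrow(sl), 1L), ]
      s <- r$lo + sample.int(r$hi - r$lo + 1L, 1L) - 1L
      e <- s + locus_len
      pl <- placed[[r$contig]]
      if (!any(s < pl$end & e > pl$start)) {
        placed[[r$contig]] <- rbind(pl, data.frame(start = s, end = e))
        loci$contig[i] <- r$contig; loci$start[i] <- s; loci$end[i] <- e
        loci$gene_id[i] <- r$gene_id
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      # deterministic first-fit over shuffled slots: only true capacity
      # exhaustion is an error
      for (si in sample.int(nrow(sl))) {
        r <- sl[si, ]
        pl <- placed[[r$contig]]
        pl <- pl[pl$end > r$lo & pl$start < r$hi + locus_len, , drop = FALSE]
        pl <- pl[order(pl$start), , drop = FALSE]
        s <- r$lo
        for (b in seq_len(nrow(pl))) {
          if (s + locus_len <= pl$start[b]) break
          s <- max(s, pl$end[b])
        }
        if (s <= r$hi) {
          e <- s + locus_len
          placed[[r$contig]] <- rbind(placed[[r$contig]],
                                      data.frame(start = s, end = e))
          loci$contig[i] <- r$contig; loci$start[i] <- s; loci$end[i] <- e
          loci$gene_id[i] <- r$gene_id
          ok <- TRUE
          break
        }
      }
    }
    if (!ok) stop("could not place locus ", i,
                  ": genome too dense, increase n_genes or contig size",
                  call. = FALSE)
  }

  # ---- batch loci, then planted loci among the rest ----
  n_batch <- floor(config$batch_loci_fraction * config$n_loci)
  batch_idx <- if (n_batch > 0) sample.int(config$n_loci, n_batch) else integer()

  planted <- config$planted
  planted_idx <- integer(nrow(planted))
  taken <- rep(FALSE, config$n_loci)
  taken[batch_idx] <- TRUE
  for (p in seq_len(nrow(planted))) {
    cand <- which(category == planted$element_class[p] & !taken)
    if (!length(cand))
      stop("no unplanted locus available for planted element class '",
           planted$element_class[p], "'", call. = FALSE)
    planted_idx[p] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    taken[planted_idx[p]] <- TRUE
  }

  # motifs: planted loci are AT-rich, mirroring the low motif GC observed
  # among expanded repeats
  mlen <- sample(seq(config$motif_length_range[1], config$motif_length_range[2]),
                 config$n_loci, replace = TRUE)
  is_planted_locus <- seq_len(config$n_loci) %in% planted_idx
  loci$motif <- vapply(seq_len(config$n_loci), function(i)
    .random_motif(mlen[i], at_rich = is_planted_locus[i]), character(1))
  loci$locus_id <- sprintf("%s:%d-%d:%s", loci$contig, loci$start, loci$end,
                           loci$motif)

  # ---- carrier assignment ----
  case_ids <- sample_id[cohort == "case"]
  ctrl_ids <- sample_id[cohort == "control"]
  ref_ids <- sample_id[cohort == "reference"]
  carrier <- matrix(FALSE, config$n_loci, n_s,
                    dimnames = list(loci$locus_id, sample_id))
  mult <- matrix(5, config$n_loci, n_s,
                 dimnames = list(loci$locus_id, sample_id))
  carriers_rec <- list()
  for (p in seq_len(nrow(planted))) {
    li <- planted_idx[p]
    pick <- c(if (planted$n_case[p]) sample(case_ids, planted$n_case[p]),
              if (planted$n_control[p]) sample(ctrl_ids, planted$n_control[p]),
              if (planted$n_reference[p]) sample(ref_ids, planted$n_reference[p]))
    carrier[li, pick] <- TRUE
    mult[li, pick] <- planted$multiplier[p]
    if (length(pick))
      carriers_rec[[p]] <- data.frame(sample_id = pick,
                                      locus_id = loci$locus_id[li],
                                      planted = TRUE)
  }
  prox_cat <- category %in% c("exon", "intron_proximal", "utr5", "utr3")
  null_rate <- config$null_expansion_rate *
    ifelse(prox_cat, config$null_exon_proximal_factor, 1)
  null_carrier <- (matrix(stats::runif(config$n_loci * n_s),
                          config$n_loci, n_s) < null_rate) & !carrier
  carrier_all <- carrier | null_carrier

  # ---- outlier samples ----
  n_out <- config$outlier_sample_count
  outlier_ids <- if (n_out > 0) sample(c(case_ids, ctrl_ids), n_out) else character()
  det_rate <- rep(config$background_detect_rate, n_s)
  det_rate[sample_id %in% outlier_ids] <-
    pmin(0.99, config$background_detect_rate * config$outlier_detect_multiplier)

  # ---- sizes ----
  baseline <- config$baseline_median *
    exp(stats::rnorm(config$n_loci, 0, config$baseline_spread))
  bg <- baseline * exp(matrix(stats::rnorm(config$n_loci * n_s, 0,
                                           config$size_noise),
                              config$n_loci, n_s))
  expn <- baseline * mult *
    exp(matrix(stats::rnorm(config$n_loci * n_s, 0, config$carrier_noise),
               config$n_loci, n_s))
  size_true <- ifelse(carrier_all, expn, bg)

  if (length(batch_idx)) {
    shift_cols <- cohort == config$batch_cohort
    size_true[batch_idx, shift_cols] <-
      size_true[batch_idx, shift_cols] * config$batch_shift
  }

  detected <- matrix(stats::runif(config$n_loci * n_s), config$n_loci, n_s) <
    matrix(det_rate, config$n_loci, n_s, byrow = TRUE) | carrier_all

  # depth round-trip: counts scale with depth, emitted sizes normalized back
  depth_m <- matrix(depth, config$n_loci, n_s, byrow = TRUE)
  emitted <- (size_true * depth_m) / depth_m
  emitted[!detected] <- NA_real_
  dimnames(emitted) <- list(loci$locus_id, sample_id)

  mat <- size_matrix(loci[, c("contig", "start", "end", "motif", "locus_id")],
                     sample_id, emitted)

  null_rec <- which(null_carrier, arr.ind = TRUE)
  carriers <- rbind(
    do.call(rbind, carriers_rec),
    if (nrow(null_rec))
      data.frame(sample_id = sample_id[null_rec[, 2]],
                 locus_id = loci$locus_id[null_rec[, 1]],
                 planted = FALSE)
  )
  rownames(carriers) <- NULL

  locus_elements <- data.frame(
    locus_id = loci$locus_id,
    element_class = .category_to_class(loci$category),
    exon_proximal = loci$category %in% c("exon", "intron_proximal",
                                         "utr5", "utr3"),
    gene_id = loci$gene_id,
    category = loci$category,
    stringsAsFactors = FALSE
  )

  truth <- list(
    carriers = carriers,
    locus_elements = locus_elements,
    planted_loci = data.frame(locus_id = loci$locus_id[planted_idx],
                              element_class = planted$element_class,
                              multiplier = planted$multiplier,
                              stringsAsFactors = FALSE),
    batch_loci = loci$locus_id[batch_idx],
    outlier_samples = outlier_ids
  )
  class(truth) <- "truth_table"

  list(matrix = mat, samples = samples, truth = truth)
}

#' Generate gene sets, constraint scores and a GWAS gene list
#'
#' Emits the downstream-analysis resources over a synthetic gene universe
#' that contains the toy genome's genes plus background filler genes: gene
#' sets with sizes spanning the 5-1000 testing bounds (including
#' deliberately out-of-bounds sets of size 4 and 1001), a LOEUF-like
#' constraint score table in which designated constrained genes (including
#' the annotated genes, which host the planted expansions) score lower, and
#' a GWAS gene list overlapping a configurable number of annotated genes.
#'
#' RNG stream: \code{config$seed + 3L}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param models Gene models from \code{\link{simulate_annotation}}.
#' @param n_universe Total gene universe size.
#' @param n_sets Number of gene sets (in addition to the two boundary sets).
#' @param n_enriched Number of sets enriched in annotated genes.
#' @param gwas_overlap Number of annotated genes included in the GWAS list.
#' @param gwas_size Total GWAS gene list size.
#' @return List with \code{universe}, \code{gene_sets} (named list of
#'   character vectors), \code{set_descriptions}, \code{constraint} (data
#'   frame \code{gene_id}, \code{score}), \code{constrained_genes},
#'   \code{gwas_genes}.
#' @export
simulate_gene_resources <- function(config, models, n_universe = 2500L,
                                    n_sets = 25L, n_enriched = 5L,
                                    gwas_overlap = 5L, gwas_size = 100L) {
  validate_sim_config(config)
  stopifnot(inherits(models, "gene_models"))
  set.seed(config$seed + 3L)
  anno_genes <- models$genes$gene_id
  n_bg <- n_universe - length(anno_genes)
  if (n_bg < 1100L) stop("n_universe too small", call. = FALSE)
  universe <- c(anno_genes, sprintf("bg%04d", seq_len(n_bg)))

  constrained <- c(anno_genes, sample(universe[-seq_along(anno_genes)], 50L))
  score <- stats::rlnorm(length(universe), meanlog = log(0.9), sdlog = 0.45)
  score[universe %in% constrained] <-
    score[universe %in% constrained] * 0.5
  constraint <- data.frame(gene_id = universe, score = score,
                           stringsAsFactors = FALSE)

  sets <- list(); descr <- character()
  for (i in seq_len(n_sets)) {
    id <- sprintf("SET%03d", i)
    if (i <= n_enriched) {
      k <- min(length(anno_genes), 15L)
      members <- c(sample(anno_genes, k),
                   sample(universe[-seq_along(anno_genes)], sample(10:60, 1L)))
      descr[id] <- sprintf("enriched set %d (annotated-gene heavy)", i)
    } else {
      members <- sample(universe, sample(5:300, 1L))
      descr[id] <- sprintf("background set %d", i)
    }
    sets[[id]] <- unique(members)
  }
  sets[["SET_TOO_SMALL"]] <- sample(universe, 4L)
  descr["SET_TOO_SMALL"] <- "below minimum testable size"
  sets[["SET_TOO_BIG"]] <- sample(universe, 1001L)
  descr["SET_TOO_BIG"] <- "above maximum testable size"

  gwas_genes <- c(sample(anno_genes, min(gwas_overlap, length(anno_genes))),
                  sample(universe[-seq_along(anno_genes)],
                         gwas_size - gwas_overlap))

  list(universe = universe, gene_sets = sets, set_descriptions = descr,
       constraint = constraint, constrained_genes = constrained,
       gwas_genes = gwas_genes)
}

#' Write a full synthetic study to a directory
#'
#' Runs \code{\link{simulate_annotation}}, \code{\link{simulate_cohort}} and
#' \code{\link{simulate_gene_resources}} and writes every on-disk artifact:
#' profile TSV, sample TSV, gene-model TSV + GFF3, element BED, gene-set
#' TSV, constraint TSV, GWAS gene list and truth JSON. Identical
#' configurations produce byte-identical files.
#'
#' @param config A \code{\link{sim_config}}.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of file paths.
#' @export
simulate_to_dir <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- simulate_annotation(config)
  cohort <- simulate_cohort(config, models)
  res <- simulate_gene_resources(config, models)

  paths <- list(
    profile = file.path(out_dir, "profile.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    gene_models = file.path(out_dir, "gene_models.tsv"),
    gff3 = file.path(out_dir, "gene_models.gff3"),
    elements = file.path(out_dir, "elements.bed"),
    gene_sets = file.path(out_dir, "gene_sets.tsv"),
    constraint = file.path(out_dir, "constraint.tsv"),
    gwas_genes = file.path(out_dir, "gwas_genes.txt"),
    truth = file.path(out_dir, "truth.json")
  )
  write_profile(cohort$matrix, paths$profile)
  write_samples(cohort$samples, paths$samples)
  write_gene_models(models, paths$gene_models)
  write_gff3(models, paths$gff3)
  elements <- partition_elements(models, annotation_params())
  write_bed(data.frame(contig = elements$contig, start = elements$start,
                       end = elements$end, name = elements$element_class),
            paths$elements)
  write_gene_sets(res$gene_sets, res$set_descriptions, paths$gene_sets)
  write_constraint(res$constraint, paths$constraint)
  writeLines(res$gwas_genes, paths$gwas_genes)
  write_truth(cohort$truth, paths$truth)
  invisible(paths)
}

#' @export
print.truth_table <- function(x, ...) {
  cat("Synthetic ground truth\n")
  cat(sprintf("  carriers: %d (%d planted, %d exchangeable)\n",
              nrow(x$carriers), sum(x$carriers$planted),
              sum(!x$carriers$planted)))
  cat(sprintf("  planted loci: %d; batch loci: %d; outlier samples: %d\n",
              nrow(x$planted_loci), length(x$batch_loci),
              length(x$outlier_samples)))
  invisible(x)
}
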