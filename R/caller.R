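#' Expansion-caller parameters
#'
#' @param min_pts DBSCAN core-point threshold (neighborhood size counting
#'   the point itself; default 11, the selected value from the grid
#'   search).
#' @param eps_multiplier DBSCAN radius as a multiple of the per-locus mode
#'   of observed sizes (default 2).
#' @param freq_cutoff Population-frequency cutoff defining a rare expansion
#'   (default 0.005, i.e. <0.5\% of the reference panel; 0.05 is the other
#'   conventional choice and is reachable here).
#' @param merge_distance Single-linkage merge distance in bp for collapsing
#'   rare-call loci into distinct regions (default 500).
#' @param mode_bin Rounding granularity (in size units) used when taking
#'   the per-locus mode (default 0.01).
#' @param reference_in_clustering Include the reference panel's sizes in
#'   the per-locus clustering (default TRUE); when FALSE the panel is used
#'   only for frequency estimation.
#' @return An object of class \code{caller_params}.
#' @export
caller_params <- function(min_pts = 11L, eps_multiplier = 2.0,
                          freq_cutoff = 0.005, merge_distance = 500L,
                          mode_bin = 0.01, reference_in_clustering = TRUE) {
  if (min_pts < 2L) stop("min_pts must be >= 2", call. = FALSE)
  if (eps_multiplier <= 0) stop("eps_multiplier must be > 0", call. = FALSE)
  if (freq_cutoff <= 0 || freq_cutoff >= 1)
    stop("freq_cutoff must be in (0, 1)", call. = FALSE)
  structure(list(min_pts = as.integer(min_pts),
                 eps_multiplier = eps_multiplier,
                 freq_cutoff = freq_cutoff,
                 merge_distance = as.integer(merge_distance),
                 mode_bin = mode_bin,
                 reference_in_clustering = reference_in_clustering),
            class = "caller_params")
}

#' Mode of observed sizes at a locus
#'
#' Sizes are rounded to \code{mode_bin} and the most frequent rounded value
#' is returned; ties break to the smallest value.
#'
#' @param sizes Observed (non-missing) size vector.
#' @param mode_bin Rounding granularity.
#' @return The modal size.
#' @export
locus_mode <- function(sizes, mode_bin = 0.01) {
  sizes <- sizes[!is.na(sizes)]
  if (!length(sizes)) stop("no observed sizes", call. = FALSE)
  r <- round(sizes / mode_bin) * mode_bin
  u <- sort(unique(r))
  counts <- vapply(u, function(v) sum(r == v), integer(1))
  u[which.max(counts)]  # first maximum = smallest value on ties
}

#' One-dimensional DBSCAN
#'
#' Classical DBSCAN on the real line: the neighborhood of a point is the
#' closed interval of radius \code{eps}; a point is core iff at least
#' \code{min_pts} points (counting itself) fall in its neighborhood. Two
#' core points share a cluster iff they are chained by core points with
#' consecutive gaps at most \code{eps}; a non-core point within \code{eps}
#' of a core point is a border point of the cluster of the leftmost such
#' core (which is what breadth-first expansion seeded in ascending order
#' produces); all other points are noise.
#'
#' @param x Numeric vector.
#' @param eps Neighborhood radius (> 0).
#' @param min_pts Core threshold.
#' @return Integer labels in input order: 0 = noise, clusters numbered from
#'   1 by order of first appearance in sorted order.
#' @export
dbscan_1d <- function(x, eps, min_pts) {
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  n <- length(x)
  if (!n) return(integer())
  ord <- order(x)
  xs <- x[ord]
  hi <- findInterval(xs + eps, xs)                      # points <= x + eps
  lo <- findInterval(xs - eps, xs, left.open = TRUE)    # points <  x - eps
  core <- (hi - lo) >= min_pts

  labels_s <- integer(n)
  if (any(core)) {
    ci <- which(core)
    xc <- xs[ci]
    # group cores chained by gaps <= eps
    brk <- c(FALSE, diff(xc) > eps)
    grp <- cumsum(brk) + 1L
    labels_s[ci] <- grp
    # border points: leftmost core within eps
    nb <- which(!core)
    if (length(nb)) {
      pos <- findInterval(xs[nb] - eps, xc, left.open = TRUE) + 1L
      okb <- pos <= length(xc) & (xc[pmin(pos, length(xc))] <= xs[nb] + eps)
      labels_s[nb[okb]] <- grp[pos[okb]]
    }
  }
  labels <- integer(n)
  labels[ord] <- labels_s
  labels
}

#' Call expansion outliers per locus
#'
#' At each locus, DBSCAN is run over the observed sizes of all samples with
#' \code{eps = max(eps_multiplier * mode, 1e-6)}; noise points whose size
#' exceeds the maximum size inside any cluster are called expansions
#' (upper-tail only: contractions are never called). Samples without signal
#' at the locus are excluded from the clustering, not imputed as zero. When
#' no cluster forms (fewer than \code{min_pts} observed samples), every
#' observed sample becomes a candidate call and the population-frequency
#' filter alone governs rarity there.
#'
#' @param mat A \code{\link{size_matrix}} (after QC).
#' @param params A \code{\link{caller_params}}.
#' @param samples Optional sample metadata; when provided and
#'   \code{reference_in_clustering} is FALSE, reference samples are left
#'   out of the clustering (but still receive candidate calls at
#'   clusterless loci only through their own observation).
#' @return Data frame of calls: \code{sample_id}, \code{locus_id},
#'   \code{contig}, \code{start}, \code{end}, \code{motif}, \code{size},
#'   sorted by locus then sample, invariant to input row/column order.
#' @export
call_expansions <- function(mat, params = caller_params(), samples = NULL) {
  stopifnot(inherits(mat, "size_matrix"))
  cluster_ids <- mat$samples
  if (!params$reference_in_clustering && !is.null(samples)) {
    nonref <- samples$sample_id[samples$cohort != "reference"]
    cluster_ids <- intersect(mat$samples, nonref)
  }
  out <- vector("list", nrow(mat$loci))
  for (i in seq_len(nrow(mat$loci))) {
    row <- mat$sizes[i, ]
    obs <- row[!is.na(row)]
    if (!length(obs)) next
    clus_obs <- obs[names(obs) %in% cluster_ids]
    if (length(clus_obs)) {
      eps <- max(params$eps_multiplier * locus_mode(clus_obs, params$mode_bin),
                 1e-6)
      labels <- dbscan_1d(unname(obs), eps, params$min_pts)
    } else labels <- rep(0L, length(obs))
    if (any(labels > 0L)) {
      cmax <- max(obs[labels > 0L])
      called <- labels == 0L & obs > cmax
    } else {
      called <- rep(TRUE, length(obs))  # no cluster: all observed are candidates
    }
    if (any(called))
      out[[i]] <- data.frame(sample_id = names(obs)[called],
                             locus_id = mat$loci$locus_id[i],
                             size = unname(obs[called]),
                             stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  if (is.null(calls))
    calls <- data.frame(sample_id = character(), locus_id = character(),
                        size = numeric(), stringsAsFactors = FALSE)
  idx <- match(calls$locus_id, mat$loci$locus_id)
  calls$contig <- mat$loci$contig[idx]
  calls$start <- mat$loci$start[idx]
  calls$end <- mat$loci$end[idx]
  calls$motif <- mat$loci$motif[idx]
  calls <- calls[order(calls$contig, calls$start, calls$motif,
                       calls$sample_id), ]
  rownames(calls) <- NULL
  calls[, c("sample_id", "locus_id", "contig", "start", "end", "motif",
            "size")]
}

#' Annotate calls with population frequency and rarity
#'
#' The population frequency of a called locus is the proportion of
#' reference-panel samples called expanded there; a call is rare when that
#' frequency is below \code{freq_cutoff}.
#'
#' @param calls Call data frame from \code{\link{call_expansions}}.
#' @param samples Sample metadata including a non-empty reference cohort.
#' @param freq_cutoff Rarity cutoff (proportion).
#' @return Calls with added \code{population_frequency} and \code{rare}.
#' @export
population_frequency <- function(calls, samples, freq_cutoff = 0.005) {
  ref_ids <- samples$sample_id[samples$cohort == "reference"]
  if (!length(ref_ids))
    stop("reference cohort is empty: population frequency undefined",
         call. = FALSE)
  ref_calls <- calls[calls$sample_id %in% ref_ids, , drop = FALSE]
  carriers <- tapply(ref_calls$sample_id, ref_calls$locus_id,
                     function(s) length(unique(s)))
  freq <- carriers[calls$locus_id] / length(ref_ids)
  freq[is.na(freq)] <- 0
  calls$population_frequency <- as.vector(freq)
  calls$rare <- calls$population_frequency < freq_cutoff
  calls
}

#' Merge rare-call loci into distinct regions
#'
#' Single-linkage merge of called loci on the same contig whose intervals
#' lie within \code{merge_distance} bp of each other, motif-agnostic: a
#' chain A-B-C with consecutive gaps below the distance forms one region.
#'
#' @param calls Rare calls (annotated or raw).
#' @param merge_distance Maximum gap in bp.
#' @return Data frame of regions: \code{region_id}, \code{contig},
#'   \code{start}, \code{end}, \code{n_loci}, \code{loci} (comma-joined),
#'   \code{motifs}, \code{n_carriers}.
#' @export
merge_regions <- function(calls, merge_distance = 500L) {
  if (!nrow(calls))
    return(data.frame(region_id = character(), contig = character(),
                      start = integer(), end = integer(), n_loci = integer(),
                      loci = character(), motifs = character(),
                      n_carriers = integer(), stringsAsFactors = FALSE))
  loci <- unique(calls[, c("locus_id", "contig", "start", "end", "motif")])
  loci <- loci[order(loci$contig, loci$start, loci$end), ]
  # single linkage: track the running max end within the current region
  region <- integer(nrow(loci))
  region[1] <- 1L
  run_end <- loci$end[1]
  for (i in seq_len(nrow(loci))[-1]) {
    if (loci$contig[i] == loci$contig[i - 1] &&
        loci$start[i] - run_end <= merge_distance) {
      region[i] <- region[i - 1]
      run_end <- max(run_end, loci$end[i])
    } else {
      region[i] <- region[i - 1] + 1L
      run_end <- loci$end[i]
    }
  }
  out <- do.call(rbind, lapply(split(loci, region), function(m) {
    ids <- m$locus_id
    data.frame(contig = m$contig[1], start = min(m$start), end = max(m$end),
               n_loci = nrow(m), loci = paste(ids, collapse = ","),
               motifs = paste(unique(m$motif), collapse = ","),
               n_carriers = length(unique(
                 calls$sample_id[calls$locus_id %in% ids])),
               stringsAsFactors = FALSE)
  }))
  out$region_id <- sprintf("region%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("region_id", "contig", "start", "end", "n_loci", "loci", "motifs",
          "n_carriers")]
}

#' Grid search over caller parameters
#'
#' For every combination of \code{min_pts}, \code{eps_multiplier} and
#' \code{freq_cutoff}, calls expansions, applies the frequency filter,
#' annotates, and runs the case-control burden test for the exon-proximal
#' and the intergenic class (total rare-call count as covariate). The
#' selected combination maximizes the exon-proximal one-sided Wald z minus
#' the intergenic one-sided Wald z: strongest biological signal, weakest
#' signal where none is expected. A degenerate (uncallable) test
#' contributes z = 0.
#'
#' @param mat A \code{\link{size_matrix}} (after QC).
#' @param samples Sample metadata.
#' @param models Gene models for annotation.
#' @param grid Data frame (or list passed to \code{expand.grid}) with
#'   columns \code{min_pts}, \code{eps_multiplier}, \code{freq_cutoff}.
#' @param annotation An \code{\link{annotation_params}}.
#' @return Data frame: one row per grid point with exonic/intergenic z and
#'   one-sided p, and a \code{selected} flag (exactly one TRUE).
#' @export
optimize_parameters <- function(mat, samples, models, grid,
                                annotation = annotation_params()) {
  if (!is.data.frame(grid)) grid <- expand.grid(grid)
  if (!nrow(grid)) stop("empty parameter grid", call. = FALSE)
  need <- c("min_pts", "eps_multiplier", "freq_cutoff")
  if (!all(need %in% names(grid)))
    stop("grid needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  elements <- partition_elements(models, annotation)
  res <- grid
  res$z_exonic <- res$p_exonic <- res$z_intergenic <- res$p_intergenic <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cp <- caller_params(min_pts = grid$min_pts[i],
                        eps_multiplier = grid$eps_multiplier[i],
                        freq_cutoff = grid$freq_cutoff[i])
    calls <- call_expansions(mat, cp)
    calls <- population_frequency(calls, samples, cp$freq_cutoff)
    rare <- calls[calls$rare, , drop = FALSE]
    ann <- annotate_calls(rare, elements, annotation)
    bz <- function(class_label) {
      fit <- tre_burden(ann, samples, class_label, n_permutations = 0L)
      if (is.na(fit$wald_z)) c(0, 0.5) else c(fit$wald_z, fit$wald_p_one_sided)
    }
    ex <- bz("exon_proximal"); ig <- bz("intergenic")
    res$z_exonic[i] <- ex[1]; res$p_exonic[i] <- ex[2]
    res$z_intergenic[i] <- ig[1]; res$p_intergenic[i] <- ig[2]
  }
  score <- res$z_exonic - res$z_intergenic
  res$selected <- seq_len(nrow(res)) == which.max(score)
  res
}
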