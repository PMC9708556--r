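#' Annotation parameters
#'
#' @param flank_size Upstream/downstream flank in bp around the TSS / TES
#'   (default 1000).
#' @param exon_proximal_window Maximum distance in bp from an exon junction
#'   for an intronic/UTR call to count as exon-proximal (default 300,
#'   strict: distance must be < window).
#' @param core_splice_size Size in bp of the core splice site at each end
#'   of an intron (default 2, the canonical donor/acceptor dinucleotides).
#' @return An object of class \code{annotation_params}.
#' @export
annotation_params <- function(flank_size = 1000L, exon_proximal_window = 300L,
                              core_splice_size = 2L) {
  if (flank_size <= 0 || exon_proximal_window <= 0 || core_splice_size <= 0)
    stop("annotation parameters must be positive", call. = FALSE)
  structure(list(flank_size = as.integer(flank_size),
                 exon_proximal_window = as.integer(exon_proximal_window),
                 core_splice_size = as.integer(core_splice_size)),
            class = "annotation_params")
}

# Impact precedence used when a call overlaps several elements: splicing and
# coding consequences outrank regulatory flanks, introns rank last among
# genic classes.
.element_priority <- c(core_splice_site = 1L, exon = 2L, utr5 = 3L, utr3 = 4L,
                       upstream = 5L, downstream = 6L, intron = 7L,
                       intergenic = 8L)

#' Partition gene models into functional elements
#'
#' Produces strand-aware intervals for the seven genic element classes:
#' upstream (flank before the TSS), 5'UTR, exon (coding exon portions),
#' core splice site (the first and last \code{core_splice_size} bp of each
#' intron), intron (the remainder), 3'UTR, and downstream (flank after the
#' TES). Anything not covered by a genic element is intergenic by
#' implication. All coordinates 0-based half-open.
#'
#' @param models A \code{gene_models} object.
#' @param params An \code{\link{annotation_params}}.
#' @return Data frame: \code{contig}, \code{start}, \code{end},
#'   \code{element_class}, \code{gene_id}, \code{strand}.
#' @export
partition_elements <- function(models, params = annotation_params()) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  css <- params$core_splice_size
  out <- list()
  add <- function(contig, start, end, cls, gid, strand) {
    keep <- end > start
    if (any(keep))
      out[[length(out) + 1L]] <<- data.frame(
        contig = contig, start = start[keep], end = end[keep],
        element_class = cls, gene_id = gid, strand = strand,
        stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]; ctg <- g$contig[i]; strand <- g$strand[i]
    e <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
    e <- e[order(e$start), ]
    cds <- models$cds[models$cds$gene_id == gid, , drop = FALSE]
    u5 <- models$utr5[models$utr5$gene_id == gid, , drop = FALSE]
    u3 <- models$utr3[models$utr3$gene_id == gid, , drop = FALSE]

    add(ctg, cds$start, cds$end, "exon", gid, strand)
    add(ctg, u5$start, u5$end, "utr5", gid, strand)
    add(ctg, u3$start, u3$end, "utr3", gid, strand)
    if (nrow(e) > 1L) {
      is_ <- e$end[-nrow(e)]; ie_ <- e$start[-1]
      add(ctg, is_, pmin(is_ + css, ie_), "core_splice_site", gid, strand)
      add(ctg, pmax(ie_ - css, is_), ie_, "core_splice_site", gid, strand)
      add(ctg, is_ + css, ie_ - css, "intron", gid, strand)
    }
    if (strand == "+") {
      add(ctg, g$start[i] - params$flank_size, g$start[i], "upstream", gid, strand)
      add(ctg, g$end[i], g$end[i] + params$flank_size, "downstream", gid, strand)
    } else {
      add(ctg, g$end[i], g$end[i] + params$flank_size, "upstream", gid, strand)
      add(ctg, g$start[i] - params$flank_size, g$start[i], "downstream", gid, strand)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2  # half-open

#' Assign each call a single prioritized element class
#'
#' All elements overlapping a call are collected and a single class is
#' assigned by the impact precedence core splice site > exon > 5'UTR >
#' 3'UTR > upstream > downstream > intron > intergenic; among equal-class
#' overlaps from different genes the smallest gene id wins (deterministic).
#' The distance to the nearest exon junction (any exon start/end of the
#' assigned gene, 0 when the call overlaps an exon) and the exon-proximal
#' flag are computed per call: a call is exon-proximal when it is in an
#' exon, or in an intron/UTR strictly closer than
#' \code{exon_proximal_window} bp to a junction. Calls on contigs absent
#' from the annotation are intergenic, with a warning.
#'
#' @param calls Call data frame (needs \code{contig}, \code{start},
#'   \code{end}).
#' @param elements Element intervals from \code{\link{partition_elements}}.
#' @param params An \code{\link{annotation_params}}.
#' @param models Optional \code{gene_models}; when supplied, exon-junction
#'   distances use the full exon intervals of the assigned gene (otherwise
#'   junctions are reconstructed from the element partition).
#' @return Calls with added \code{element_class}, \code{gene_id},
#'   \code{distance_to_exon_junction}, \code{exon_proximal}.
#' @export
annotate_calls <- function(calls, elements, params = annotation_params(),
                           models = NULL) {
  n <- nrow(calls)
  cls <- rep("intergenic", n)
  gid <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  prox <- rep(FALSE, n)
  if (!n) {
    calls$element_class <- character(); calls$gene_id <- character()
    calls$distance_to_exon_junction <- integer()
    calls$exon_proximal <- logical()
    return(calls)
  }
  exon_iv <- if (!is.null(models)) {
    merge(models$exons, models$genes[, c("gene_id", "contig")], by = "gene_id")
  } else {
    # reconstruct transcript exons as union of coding exon + UTR elements
    ex <- elements[elements$element_class %in% c("exon", "utr5", "utr3"), ,
                   drop = FALSE]
    ex[, c("gene_id", "start", "end", "contig")]
  }
  known_contigs <- unique(elements$contig)
  warned <- FALSE
  for (i in seq_len(n)) {
    cs <- calls$start[i]; ce <- calls$end[i]; ctg <- calls$contig[i]
    if (!ctg %in% known_contigs) {
      if (!warned) {
        warning("call contig(s) absent from annotation; treated as intergenic",
                call. = FALSE)
        warned <- TRUE
      }
      next
    }
    hit <- elements[elements$contig == ctg &
                      .overlaps(elements$start, elements$end, cs, ce), ,
                    drop = FALSE]
    if (!nrow(hit)) next
    pri <- .element_priority[hit$element_class]
    best <- hit[order(pri, hit$gene_id), ][1, ]
    cls[i] <- best$element_class
    gid[i] <- best$gene_id

    ej <- exon_iv[exon_iv$gene_id == best$gene_id, , drop = FALSE]
    if (nrow(ej)) {
      if (any(.overlaps(ej$start, ej$end, cs, ce))) {
        dist[i] <- 0L
      } else {
        # gap between half-open intervals
        d <- pmax(ej$start - ce, cs - ej$end)
        dist[i] <- as.integer(min(d))
      }
      prox[i] <- cls[i] == "exon" ||
        (cls[i] %in% c("intron", "utr5", "utr3") &&
           dist[i] < params$exon_proximal_window)
    }
  }
  calls$element_class <- cls
  calls$gene_id <- gid
  calls$distance_to_exon_junction <- dist
  calls$exon_proximal <- prox
  calls
}

#' Canonical motif representative
#'
#' The lexicographically smallest string among all cyclic rotations of the
#' motif and of its reverse complement, so that equivalent repeat motifs
#' aggregate to one label. Idempotent.
#'
#' @param motif DNA motif (A/C/G/T).
#' @return Canonical motif string.
#' @examples
#' canonical_motif("TTC")  # "AAG"
#' @export
canonical_motif <- function(motif) {
  if (length(motif) != 1L || !grepl("^[ACGT]+$", motif))
    stop("motif must be a non-empty ACGT string", call. = FALSE)
  rot <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n), function(i)
      paste0(substr(s, i, n), substr(s, 1, i - 1L)), character(1))
  }
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", motif), "")[[1]]),
              collapse = "")
  min(c(rot(motif), rot(rc)))
}

#' Motif GC content
#'
#' @param motif DNA motif (A/C/G/T).
#' @return Proportion of G or C bases.
#' @export
motif_gc <- function(motif) {
  if (length(motif) != 1L || !nzchar(motif))
    stop("empty motif", call. = FALSE)
  if (!grepl("^[ACGT]+$", motif))
    stop("motif must be an ACGT string", call. = FALSE)
  b <- strsplit(motif, "")[[1]]
  sum(b %in% c("G", "C")) / length(b)
}
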