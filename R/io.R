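#' Multisample repeat-size profile container
#'
#' A \code{size_matrix} holds per-locus, per-sample depth-normalized
#' repeat-size estimates. Missing entries (\code{NA}) mean no signal: the
#' repeat tract in that sample was below the detection limit (shorter than
#' the read length), not size zero.
#'
#' @param loci Data frame with columns \code{contig}, \code{start},
#'   \code{end} (0-based half-open), \code{motif}, \code{locus_id}.
#' @param samples Character vector of unique sample ids.
#' @param sizes Numeric matrix, loci x samples; non-negative or \code{NA}.
#' @return An object of class \code{size_matrix}.
#' @export
size_matrix <- function(loci, samples, sizes) {
  stopifnot(is.data.frame(loci), is.character(samples), is.matrix(sizes))
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus ids", call. = FALSE)
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  if (nrow(sizes) != nrow(loci) || ncol(sizes) != length(samples))
    stop("size matrix dimensions do not match loci/samples", call. = FALSE)
  if (any(sizes < 0, na.rm = TRUE))
    stop("sizes must be non-negative where present", call. = FALSE)
  if (any(loci$end <= loci$start))
    stop("locus end must exceed start", call. = FALSE)
  dimnames(sizes) <- list(loci$locus_id, samples)
  structure(list(loci = loci, samples = samples, sizes = sizes),
            class = "size_matrix")
}

#' @export
print.size_matrix <- function(x, ...) {
  obs <- sum(!is.na(x$sizes))
  cat(sprintf("Repeat size profile: %d loci x %d samples (%.1f%% observed)\n",
              nrow(x$loci), length(x$samples),
              100 * obs / length(x$sizes)))
  invisible(x)
}

#' @export
dim.size_matrix <- function(x) dim(x$sizes)

.io_stop <- function(path, line, msg) {
  stop(sprintf("%s:%s: %s", path, if (is.null(line)) "?" else line, msg),
       call. = FALSE)
}

#' Parse and format locus identifiers
#'
#' Locus ids have the form \code{"contig:start-end:motif"} with 0-based
#' half-open coordinates; parse and format round-trip exactly.
#'
#' @param ids Character vector of locus ids.
#' @return \code{parse_locus_id}: data frame with \code{contig},
#'   \code{start}, \code{end}, \code{motif}, \code{locus_id}.
#' @export
parse_locus_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+):([ACGT]{2,20})$", ids))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stop("malformed locus id: ", ids[which(bad)[1]], call. = FALSE)
  data.frame(
    contig = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    motif = vapply(m, `[`, "", 5L),
    locus_id = ids,
    stringsAsFactors = FALSE
  )
}

#' @rdname parse_locus_id
#' @param loci Data frame with \code{contig}, \code{start}, \code{end},
#'   \code{motif}.
#' @export
format_locus_id <- function(loci) {
  sprintf("%s:%d-%d:%s", loci$contig, loci$start, loci$end, loci$motif)
}

.fmt_size <- function(x) ifelse(is.na(x), ".", sprintf("%.6g", x))

#' Read and write multisample size-profile TSVs
#'
#' Dialect: a header line \code{#contig start end motif <sample1> ...}
#' (tab-separated), one row per locus, missing cells written as \code{"."},
#' sizes printed with 6 significant digits. Input locus order is preserved.
#' Readers reject malformed input (bad motif, non-numeric size, duplicate
#' locus) with file and line context rather than coercing.
#'
#' @param path File path.
#' @return \code{read_profile}: a \code{\link{size_matrix}}.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    .io_stop(path, 1L, "missing '#contig start end motif ...' header")
  hdr <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 5L || !identical(hdr[1:4], c("contig", "start", "end", "motif")))
    .io_stop(path, 1L, "header must be contig, start, end, motif, <samples>")
  samples <- hdr[-(1:4)]
  if (anyDuplicated(samples)) .io_stop(path, 1L, "duplicate sample ids")

  body <- lines[-1]
  body <- body[nzchar(body)]
  n <- length(body)
  loci <- data.frame(contig = character(n), start = integer(n),
                     end = integer(n), motif = character(n),
                     stringsAsFactors = FALSE)
  sizes <- matrix(NA_real_, n, length(samples))
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    ln <- i + 1L
    if (length(f) != 4L + length(samples))
      .io_stop(path, ln, sprintf("expected %d fields, found %d",
                                 4L + length(samples), length(f)))
    if (!grepl("^[ACGT]{2,20}$", f[4]))
      .io_stop(path, ln, paste0("malformed motif '", f[4], "'"))
    st <- suppressWarnings(as.integer(f[2])); en <- suppressWarnings(as.integer(f[3]))
    if (is.na(st) || is.na(en) || en <= st)
      .io_stop(path, ln, "invalid coordinates")
    id <- sprintf("%s:%d-%d:%s", f[1], st, en, f[4])
    if (!is.null(seen[[id]])) .io_stop(path, ln, paste0("duplicate locus id ", id))
    assign(id, TRUE, envir = seen)
    loci$contig[i] <- f[1]; loci$start[i] <- st; loci$end[i] <- en
    loci$motif[i] <- f[4]
    cells <- f[-(1:4)]
    vals <- suppressWarnings(as.numeric(cells))
    bad <- is.na(vals) & cells != "."
    if (any(bad))
      .io_stop(path, ln, paste0("non-numeric size '", cells[which(bad)[1]], "'"))
    sizes[i, ] <- vals
  }
  loci$locus_id <- format_locus_id(loci)
  size_matrix(loci, samples, sizes)
}

#' @rdname read_profile
#' @param mat A \code{\link{size_matrix}}.
#' @export
write_profile <- function(mat, path) {
  stopifnot(inherits(mat, "size_matrix"))
  hdr <- paste(c("#contig", "start", "end", "motif", mat$samples),
               collapse = "\t")
  cells <- matrix(.fmt_size(mat$sizes), nrow = nrow(mat$sizes))
  rows <- paste(mat$loci$contig, mat$loci$start, mat$loci$end, mat$loci$motif,
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

.cohort_levels <- c("case", "control", "reference")
.clinical_flags <- c("family_history", "intellectual_disability",
                     "syndromic_features", "early_onset",
                     "clinically_relevant_variant", "rare_cnv")

#' Read and write sample metadata tables
#'
#' Tab-separated with columns \code{sample_id}, \code{cohort} (case /
#' control / reference), \code{sex} (male / female), the boolean clinical
#' flags, and optional \code{family_id}.
#'
#' @param path File path.
#' @return \code{read_samples}: a data frame.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character"))
  if (!all(c("sample_id", "cohort", "sex") %in% names(df)))
    .io_stop(path, 1L, "need columns sample_id, cohort, sex")
  if (anyDuplicated(df$sample_id)) {
    dup <- df$sample_id[duplicated(df$sample_id)][1]
    .io_stop(path, which(df$sample_id == dup)[2] + 1L,
             paste0("duplicate sample id ", dup))
  }
  bad <- !df$cohort %in% .cohort_levels
  if (any(bad))
    .io_stop(path, which(bad)[1] + 1L,
             paste0("invalid cohort '", df$cohort[which(bad)[1]], "'"))
  for (fl in intersect(.clinical_flags, names(df)))
    df[[fl]] <- as.logical(df[[fl]])
  df
}

#' @rdname read_samples
#' @param samples Sample metadata data frame.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

validate_gene_models <- function(models, path = "<gene models>") {
  need <- c("genes", "exons")
  if (!all(need %in% names(models)))
    stop("gene models need components: ", paste(need, collapse = ", "),
         call. = FALSE)
  g <- models$genes
  for (gid in g$gene_id) {
    e <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
    if (!nrow(e)) stop(path, ": gene ", gid, " has no exons", call. = FALSE)
    e <- e[order(e$start), ]
    gs <- g$start[g$gene_id == gid]; ge <- g$end[g$gene_id == gid]
    if (any(e$start < gs) || any(e$end > ge))
      stop(path, ": exon outside gene span for ", gid, call. = FALSE)
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)]))
      stop(path, ": overlapping exons within transcript of ", gid,
           call. = FALSE)
  }
  invisible(models)
}

#' Strand-aware transcription start / end sites
#'
#' For a plus-strand gene the TSS is the lowest coordinate; for a
#' minus-strand gene it is the highest (0-based half-open spans).
#'
#' @param models A \code{gene_models} object.
#' @return \code{gene_tss}/\code{gene_tes}: named integer vector by gene id.
#' @export
gene_tss <- function(models) {
  g <- models$genes
  stats::setNames(ifelse(g$strand == "+", g$start, g$end), g$gene_id)
}

#' @rdname gene_tss
#' @export
gene_tes <- function(models) {
  g <- models$genes
  stats::setNames(ifelse(g$strand == "+", g$end, g$start), g$gene_id)
}

#' Read gene models from a gene-table TSV or GFF3
#'
#' The gene-table dialect is one row per single-transcript gene with
#' comma-joined exon/CDS interval lists (all coordinates 0-based
#' half-open). GFF3 input (\code{.gff}/\code{.gff3}) is parsed with
#' rtracklayer and converted from 1-based closed coordinates at the
#' boundary. Models are validated: exons must lie within the gene span and
#' must not overlap within a transcript.
#'
#' @param path File path (\code{.tsv} or \code{.gff3}).
#' @return A \code{gene_models} object: list of data frames \code{genes}
#'   (gene_id, contig, strand, start, end), \code{exons}, \code{cds},
#'   \code{utr5}, \code{utr3} (gene_id, start, end) and \code{contigs}.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE))
    return(.read_gene_models_gff3(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig", "strand", "start", "end",
            "exon_starts", "exon_ends")
  if (!all(need %in% names(df)))
    .io_stop(path, 1L, paste("need columns:", paste(need, collapse = ", ")))
  split_ints <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  pull <- function(scol, ecol) do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    s <- split_ints(df[[scol]][i]); e <- split_ints(df[[ecol]][i])
    if (!length(s)) return(NULL)
    data.frame(gene_id = df$gene_id[i], start = s, end = e)
  }))
  models <- list(
    genes = df[, c("gene_id", "contig", "strand", "start", "end")],
    exons = pull("exon_starts", "exon_ends"),
    cds = if ("cds_starts" %in% names(df)) pull("cds_starts", "cds_ends") else NULL,
    utr5 = if ("utr5_start" %in% names(df))
      data.frame(gene_id = df$gene_id, start = df$utr5_start, end = df$utr5_end)
      else NULL,
    utr3 = if ("utr3_start" %in% names(df))
      data.frame(gene_id = df$gene_id, start = df$utr3_start, end = df$utr3_end)
      else NULL,
    contigs = data.frame(
      contig = sort(unique(df$contig)),
      length = vapply(sort(unique(df$contig)), function(ctg)
        max(df$end[df$contig == ctg]) + 4000L, integer(1))
    )
  )
  class(models) <- "gene_models"
  validate_gene_models(models, path)
  models
}

.read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  typ <- as.character(gr$type)
  to_df <- function(sel, gene_ids) {
    if (!any(sel)) return(NULL)
    data.frame(gene_id = gene_ids[sel],
               start = GenomicRanges::start(gr)[sel] - 1L,
               end = GenomicRanges::end(gr)[sel])
  }
  # map features to their gene via Parent chains (gene <- mRNA <- exon)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parents <- vapply(seq_along(gr), function(i) {
    p <- gr$Parent[[i]]
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))
  gene_of <- function(i) {
    p <- parents[i]
    while (!is.na(p)) {
      j <- match(p, ids)
      if (is.na(j)) return(p)
      if (typ[j] == "gene") return(ids[j])
      p <- parents[j]
    }
    ids[i]
  }
  gene_ids <- vapply(seq_along(gr), gene_of, character(1))
  gsel <- typ == "gene"
  models <- list(
    genes = data.frame(
      gene_id = ids[gsel],
      contig = as.character(GenomicRanges::seqnames(gr))[gsel],
      strand = as.character(GenomicRanges::strand(gr))[gsel],
      start = GenomicRanges::start(gr)[gsel] - 1L,
      end = GenomicRanges::end(gr)[gsel]
    ),
    exons = to_df(typ == "exon", gene_ids),
    cds = to_df(typ == "CDS", gene_ids),
    utr5 = to_df(typ == "five_prime_UTR", gene_ids),
    utr3 = to_df(typ == "three_prime_UTR", gene_ids),
    contigs = NULL
  )
  ctgs <- sort(unique(models$genes$contig))
  models$contigs <- data.frame(
    contig = ctgs,
    length = vapply(ctgs, function(ctg)
      max(models$genes$end[models$genes$contig == ctg]) + 4000L, integer(1))
  )
  class(models) <- "gene_models"
  validate_gene_models(models, path)
  models
}

#' @rdname read_gene_models
#' @param models A \code{gene_models} object.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  join <- function(df, gid, col) {
    x <- df[df$gene_id == gid, , drop = FALSE]
    x <- x[order(x$start), ]
    paste(x[[col]], collapse = ",")
  }
  out <- data.frame(
    gene_id = g$gene_id, contig = g$contig, strand = g$strand,
    start = g$start, end = g$end,
    exon_starts = vapply(g$gene_id, join, "", df = models$exons, col = "start"),
    exon_ends = vapply(g$gene_id, join, "", df = models$exons, col = "end"),
    cds_starts = vapply(g$gene_id, join, "", df = models$cds, col = "start"),
    cds_ends = vapply(g$gene_id, join, "", df = models$cds, col = "end"),
    utr5_start = models$utr5$start[match(g$gene_id, models$utr5$gene_id)],
    utr5_end = models$utr5$end[match(g$gene_id, models$utr5$gene_id)],
    utr3_start = models$utr3$start[match(g$gene_id, models$utr3$gene_id)],
    utr3_end = models$utr3$end[match(g$gene_id, models$utr3$gene_id)]
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_gene_models
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  row <- function(ctg, type, s, e, strand, attrs)
    sprintf("%s\ttreburden\t%s\t%d\t%d\t.\t%s\t.\t%s",
            ctg, type, s + 1L, e, strand, attrs)
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]; tid <- paste0(gid, ".t1")
    lines <- c(lines,
      row(g$contig[i], "gene", g$start[i], g$end[i], g$strand[i],
          sprintf("ID=%s", gid)),
      row(g$contig[i], "mRNA", g$start[i], g$end[i], g$strand[i],
          sprintf("ID=%s;Parent=%s", tid, gid)))
    feat <- function(df, type) {
      x <- df[df$gene_id == gid, , drop = FALSE]
      if (!nrow(x)) return(character())
      x <- x[order(x$start), ]
      row(g$contig[i], type, x$start, x$end, g$strand[i],
          sprintf("Parent=%s", tid))
    }
    lines <- c(lines, feat(models$exons, "exon"), feat(models$cds, "CDS"),
               feat(models$utr5, "five_prime_UTR"),
               feat(models$utr3, "three_prime_UTR"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write BED4 interval files
#'
#' Coordinates are 0-based half-open throughout, matching the BED
#' convention; the name column carries an element class or call id.
#'
#' @param path File path.
#' @return \code{read_bed}: data frame \code{contig}, \code{start},
#'   \code{end}, \code{name}.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!length(readLines(path, n = 1L)))
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), name = character()))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("contig", "start", "end", "name")
  df[, 1:4]
}

#' @rdname read_bed
#' @param bed Data frame with \code{contig}, \code{start}, \code{end},
#'   \code{name}.
#' @export
write_bed <- function(bed, path) {
  if (!nrow(bed)) { writeLines(character(), path); return(invisible(path)) }
  writeLines(sprintf("%s\t%d\t%d\t%s", bed$contig, as.integer(bed$start),
                     as.integer(bed$end), bed$name), path)
  invisible(path)
}

#' Read and write gene-set files
#'
#' GMT-style TSV: one set per line, fields \code{set_id}, description, then
#' one gene id per remaining field.
#'
#' @param path File path.
#' @return \code{read_gene_sets}: list with \code{gene_sets} (named list)
#'   and \code{set_descriptions}.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descr <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) .io_stop(path, i, "need set_id, description, genes")
    if (!is.null(sets[[f[1]]])) .io_stop(path, i, paste0("duplicate set ", f[1]))
    sets[[f[1]]] <- f[-(1:2)]
    descr[f[1]] <- f[2]
  }
  list(gene_sets = sets, set_descriptions = descr)
}

#' @rdname read_gene_sets
#' @param sets Named list of character vectors.
#' @param descriptions Named character vector of set descriptions.
#' @export
write_gene_sets <- function(sets, descriptions, path) {
  lines <- vapply(names(sets), function(id)
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write per-gene constraint scores
#'
#' TSV with columns \code{gene_id}, \code{score} (LOEUF-like: lower = more
#' constrained; scores must be non-negative).
#'
#' @param path File path.
#' @return \code{read_constraint}: data frame \code{gene_id}, \code{score}.
#' @export
read_constraint <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "score") %in% names(df)))
    .io_stop(path, 1L, "need columns gene_id, score")
  if (any(is.na(df$score)) || any(df$score < 0))
    .io_stop(path, NULL, "scores must be non-negative numbers")
  df
}

#' @rdname read_constraint
#' @param constraint Data frame \code{gene_id}, \code{score}.
#' @export
write_constraint <- function(constraint, path) {
  out <- constraint
  out$score <- sprintf("%.6g", out$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.call_columns <- c("sample_id", "locus_id", "contig", "start", "end", "motif",
                   "size", "population_frequency", "rare", "element_class",
                   "gene_id", "distance_to_exon_junction", "exon_proximal")

#' Read and write expansion-call tables
#'
#' Calls are written as a TSV with a stable column order (raw or annotated)
#' plus a BED4 companion (same path with extension \code{.bed}) for genome
#' browsers; the BED name is \code{locus_id|sample_id}. An empty call set
#' produces a header-only TSV and an empty BED.
#'
#' @param path TSV path.
#' @return \code{read_calls}: data frame of calls.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character"))
  for (col in intersect(c("rare", "exon_proximal"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  df
}

#' @rdname read_calls
#' @param calls Data frame of calls.
#' @param bed Write the BED companion (default TRUE).
#' @export
write_calls <- function(calls, path, bed = TRUE) {
  cols <- intersect(.call_columns, names(calls))
  out <- calls[, c(cols, setdiff(names(calls), cols)), drop = FALSE]
  if ("size" %in% names(out)) out$size <- sprintf("%.6g", out$size)
  if ("population_frequency" %in% names(out))
    out$population_frequency <- sprintf("%.6g", out$population_frequency)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (bed) {
    bed_path <- sub("\\.[^.]+$", ".bed", path)
    if (identical(bed_path, path)) bed_path <- paste0(path, ".bed")
    if (nrow(calls)) {
      write_bed(data.frame(contig = calls$contig, start = calls$start,
                           end = calls$end,
                           name = paste(calls$locus_id, calls$sample_id,
                                        sep = "|")),
                bed_path)
    } else writeLines(character(), bed_path)
  }
  invisible(path)
}

#' Read and write synthetic ground truth
#'
#' The truth table (carrier map, locus element labels, planted loci, batch
#' loci, outlier samples) round-trips through JSON.
#'
#' @param path JSON path.
#' @return \code{read_truth}: a \code{truth_table} object.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$batch_loci <- as.character(x$batch_loci)
  x$outlier_samples <- as.character(x$outlier_samples)
  class(x) <- "truth_table"
  x
}

#' @rdname read_truth
#' @param truth A \code{truth_table} object.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
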