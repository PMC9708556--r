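# Shared fixtures and independent oracles used across the suite.

# Brute-force DBSCAN via explicit neighbor-graph breadth-first expansion,
# seeds processed in ascending coordinate order. Independent of the
# package's windowed implementation.
dbscan_oracle <- function(x, eps, min_pts) {
  n <- length(x)
  if (!n) return(integer())
  adj <- abs(outer(x, x, "-")) <= eps
  core <- rowSums(adj) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in order(x)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      if (!core[q]) next
      for (j in which(adj[q, ])) {
        if (labels[j] == 0L) {
          labels[j] <- cl
          if (core[j]) queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

# Full hypergeometric enumeration for the one-sided (enrichment) Fisher
# test, from first principles with choose().
hyper_enrich_p <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  K <- a + c_          # TRE genes
  n <- a + b           # set size
  ks <- max(0L, n + K - N):min(n, K)
  probs <- vapply(ks, function(k)
    choose(K, k) * choose(N - K, n - k) / choose(N, n), numeric(1))
  sum(probs[ks >= a])
}

# One-sided ("less") rank-sum p by full enumeration of group assignments.
ranksum_less_enum <- function(x, y) {
  pool <- c(x, y)
  r <- rank(pool)
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)])
  cmb <- utils::combn(length(pool), nx)
  w_all <- apply(cmb, 2L, function(idx) sum(r[idx]))
  mean(w_all <= w_obs)
}

# Two-sided Spearman p by enumeration of all permutations of y.
spearman_enum_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  obs <- stats::cor(rank(x), rank(y))
  rhos <- vapply(perms(seq_along(y)), function(p)
    stats::cor(rank(x), rank(y[p])), numeric(1))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# A minimal size matrix built from a plain sizes matrix.
toy_matrix <- function(sizes, contig = "chr1") {
  n <- nrow(sizes)
  loci <- data.frame(
    contig = contig,
    start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 50L,
    motif = rep(c("AT", "CAG", "AAAAG"), length.out = n),
    stringsAsFactors = FALSE
  )
  loci$locus_id <- format_locus_id(loci)
  if (is.null(colnames(sizes)))
    colnames(sizes) <- sprintf("s%02d", seq_len(ncol(sizes)))
  size_matrix(loci, colnames(sizes), sizes)
}

toy_samples <- function(n_case, n_control, n_reference = 0L) {
  ids <- c(sprintf("case%03d", seq_len(n_case)),
           sprintf("ctrl%03d", seq_len(n_control)),
           if (n_reference > 0) sprintf("ref%04d", seq_len(n_reference)))
  data.frame(
    sample_id = ids,
    cohort = rep(c("case", "control", "reference"),
                 c(n_case, n_control, n_reference)),
    sex = rep(c("male", "female"), length.out = length(ids)),
    family_history = FALSE, intellectual_disability = FALSE,
    syndromic_features = FALSE, early_onset = FALSE,
    clinically_relevant_variant = FALSE, rare_cnv = FALSE,
    family_id = NA_character_,
    stringsAsFactors = FALSE
  )
}

# A small but fully featured simulation config for fast end-to-end tests.
small_sim_config <- function(seed = 1L,
                             planted = default_planted_loci()[c(1, 9, 13), ],
                             ...) {
  sim_config(n_cases = 40L, n_controls = 40L, n_reference = 120L,
             n_loci = 80L, n_genes = 12L, seed = seed, planted = planted, ...)
}

# Hand-built two-exon gene models: exons [1000,1300) and [2300,2700),
# UTRs at the transcript ends, plus strand.
two_exon_models <- function(strand = "+") {
  models <- list(
    genes = data.frame(gene_id = "gA", contig = "chr1", strand = strand,
                       start = 1000L, end = 2700L),
    exons = data.frame(gene_id = "gA", start = c(1000L, 2300L),
                       end = c(1300L, 2700L)),
    cds = if (strand == "+")
      data.frame(gene_id = "gA", start = c(1100L, 2300L),
                 end = c(1300L, 2550L))
    else
      data.frame(gene_id = "gA", start = c(1150L, 2300L),
                 end = c(1300L, 2600L)),
    utr5 = if (strand == "+")
      data.frame(gene_id = "gA", start = 1000L, end = 1100L)
    else
      data.frame(gene_id = "gA", start = 2600L, end = 2700L),
    utr3 = if (strand == "+")
      data.frame(gene_id = "gA", start = 2550L, end = 2700L)
    else
      data.frame(gene_id = "gA", start = 1000L, end = 1150L),
    contigs = data.frame(contig = "chr1", length = 10000L)
  )
  class(models) <- "gene_models"
  models
}

make_call <- function(contig, start, end, sample_id = "case001",
                      motif = "CAG", rare = TRUE) {
  data.frame(sample_id = sample_id, locus_id = sprintf("%s:%d-%d:%s", contig,
                                                       start, end, motif),
             contig = contig, start = start, end = end, motif = motif,
             size = 10, rare = rare, stringsAsFactors = FALSE)
}
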