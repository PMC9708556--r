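test_that("element partition places core splice sites at intron ends", {
  models <- list(
    genes = data.frame(gene_id = "g1", contig = "chr1", strand = "+",
                       start = 0L, end = 3000L),
    exons = data.frame(gene_id = "g1", start = c(0L, 2000L),
                       end = c(1000L, 3000L)),
    cds = data.frame(gene_id = "g1", start = c(100L, 2000L),
                     end = c(1000L, 2800L)),
    utr5 = data.frame(gene_id = "g1", start = 0L, end = 100L),
    utr3 = data.frame(gene_id = "g1", start = 2800L, end = 3000L),
    contigs = data.frame(contig = "chr1", length = 5000L)
  )
  class(models) <- "gene_models"
  el <- partition_elements(models, annotation_params())
  css <- el[el$element_class == "core_splice_site", ]
  expect_identical(sort(css$start), c(1000L, 1998L))
  expect_identical(sort(css$end), c(1002L, 2000L))
  intron <- el[el$element_class == "intron", ]
  expect_identical(intron$start, 1002L)
  expect_identical(intron$end, 1998L)
})

test_that("flanks are strand-aware", {
  plus <- partition_elements(two_exon_models("+"), annotation_params())
  minus <- partition_elements(two_exon_models("-"), annotation_params())
  up_p <- plus[plus$element_class == "upstream", ]
  up_m <- minus[minus$element_class == "upstream", ]
  expect_identical(c(up_p$start, up_p$end), c(0L, 1000L))
  expect_identical(c(up_m$start, up_m$end), c(2700L, 3700L))
})

test_that("per-gene elements tile the gene body plus flanks without gaps", {
  cfg <- small_sim_config(seed = 23)
  m <- simulate_annotation(cfg)
  el <- partition_elements(m, annotation_params())
  for (gid in m$genes$gene_id[1:6]) {
    ge <- el[el$gene_id == gid, ]
    ge <- ge[order(ge$start, ge$end), ]
    # merge overlapping element intervals (exon/UTR overlap by design) and
    # verify the union is one contiguous block spanning flank to flank
    run_end <- ge$end[1]; run_start <- ge$start[1]; blocks <- 1L
    for (i in seq_len(nrow(ge))[-1]) {
      if (ge$start[i] <= run_end) run_end <- max(run_end, ge$end[i])
      else { blocks <- blocks + 1L; run_end <- ge$end[i] }
    }
    g <- m$genes[m$genes$gene_id == gid, ]
    expect_identical(blocks, 1L)
    expect_identical(run_start, g$start - 1000L)
    expect_identical(run_end, g$end + 1000L)
  }
})

test_that("overlap priority resolves to the most damaging class", {
  models <- two_exon_models("+")
  el <- partition_elements(models, annotation_params())
  # spans the exon1/intron boundary at 1300: overlaps exon, core splice
  # site, intron -> core splice site wins
  a1 <- annotate_calls(make_call("chr1", 1290L, 1310L), el,
                       annotation_params(), models)
  expect_identical(a1$element_class, "core_splice_site")
  # overlaps exon and intron but stops before the 2 bp splice core
  a2 <- annotate_calls(make_call("chr1", 1250L, 1300L), el,
                       annotation_params(), models)
  expect_identical(a2$element_class, "exon")
  expect_identical(a2$distance_to_exon_junction, 0L)
  expect_true(a2$exon_proximal)
})

test_that("the exon-proximal window is strict at 300 bp", {
  models <- two_exon_models("+")
  el <- partition_elements(models, annotation_params())
  near <- annotate_calls(make_call("chr1", 1450L, 1460L), el,
                         annotation_params(), models)
  expect_identical(near$element_class, "intron")
  expect_identical(near$distance_to_exon_junction, 150L)
  expect_true(near$exon_proximal)

  far <- annotate_calls(make_call("chr1", 1601L, 1651L), el,
                        annotation_params(), models)
  expect_identical(far$distance_to_exon_junction, 301L)
  expect_false(far$exon_proximal)

  window <- annotate_calls(make_call("chr1", 1600L, 1650L), el,
                           annotation_params(), models)
  expect_identical(window$distance_to_exon_junction, 300L)
  expect_false(window$exon_proximal)  # strictly less than the window
})

test_that("distance to exon junction is zero iff the call touches an exon", {
  models <- two_exon_models("+")
  el <- partition_elements(models, annotation_params())
  set.seed(9)
  for (s in sample(1000:2650, 25)) {
    ann <- annotate_calls(make_call("chr1", s, s + 10L), el,
                          annotation_params(), models)
    overlaps_exon <- any(s < models$exons$end & s + 10L > models$exons$start)
    expect_identical(ann$distance_to_exon_junction == 0L, overlaps_exon,
                     info = paste("start", s))
  }
})

test_that("calls outside any element are intergenic; unknown contigs warn", {
  models <- two_exon_models("+")
  el <- partition_elements(models, annotation_params())
  ig <- annotate_calls(make_call("chr1", 8000L, 8050L), el,
                       annotation_params(), models)
  expect_identical(ig$element_class, "intergenic")
  expect_true(is.na(ig$gene_id))
  expect_false(ig$exon_proximal)

  expect_warning(
    un <- annotate_calls(make_call("chrZ", 100L, 150L), el,
                         annotation_params(), models),
    "absent")
  expect_identical(un$element_class, "intergenic")
})

test_that("equal-priority multi-gene overlap resolves to the smallest id", {
  mA <- two_exon_models("+")
  mB <- two_exon_models("+")
  mB$genes$gene_id <- "gB"
  mB$exons$gene_id <- mB$cds$gene_id <- "gB"
  mB$utr5$gene_id <- mB$utr3$gene_id <- "gB"
  models <- list(
    genes = rbind(mA$genes, mB$genes), exons = rbind(mA$exons, mB$exons),
    cds = rbind(mA$cds, mB$cds), utr5 = rbind(mA$utr5, mB$utr5),
    utr3 = rbind(mA$utr3, mB$utr3), contigs = mA$contigs
  )
  class(models) <- "gene_models"
  el <- partition_elements(models, annotation_params())
  ann <- annotate_calls(make_call("chr1", 1450L, 1460L), el,
                        annotation_params(), models)
  expect_identical(ann$gene_id, "gA")
})

test_that("canonical motifs minimize over rotations and reverse complement", {
  expect_identical(canonical_motif("AGC"), "AGC")
  expect_identical(canonical_motif("TTC"), "AAG")
  expect_identical(canonical_motif("CAG"), "AGC")
  set.seed(3)
  for (i in 1:25) {
    m <- paste(sample(c("A", "C", "G", "T"), sample(2:8, 1), replace = TRUE),
               collapse = "")
    cm <- canonical_motif(m)
    expect_identical(canonical_motif(cm), cm)  # idempotent
    expect_true(cm <= m)
  }
  expect_error(canonical_motif("ANC"), "ACGT")
})

test_that("motif GC content is the G+C fraction", {
  expect_equal(motif_gc("AAAAG"), 0.2)
  expect_equal(motif_gc("CG"), 1.0)
  expect_equal(motif_gc("AT"), 0.0)
  expect_error(motif_gc(""), "empty")
  expect_error(motif_gc("AXT"), "ACGT")
})

test_that("annotation reproduces the generator's truth labels", {
  cfg <- small_sim_config(seed = 13)
  m <- simulate_annotation(cfg)
  co <- simulate_cohort(cfg, m)
  el <- partition_elements(m, annotation_params())
  loci <- co$matrix$loci
  fake_calls <- data.frame(sample_id = "x", locus_id = loci$locus_id,
                           contig = loci$contig, start = loci$start,
                           end = loci$end, motif = loci$motif, size = 10,
                           rare = TRUE, stringsAsFactors = FALSE)
  ann <- annotate_calls(fake_calls, el, annotation_params(), m)
  truth <- co$truth$locus_elements
  idx <- match(ann$locus_id, truth$locus_id)
  expect_identical(ann$element_class, truth$element_class[idx])
  expect_identical(ann$exon_proximal, truth$exon_proximal[idx])
})
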