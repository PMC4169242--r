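test_that("peak-gene association follows the 1 kb gap rule with boundary cases", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 6000),
                                  strand = "+")
  genes$gene_id <- "gA"
  # gap 900 -> associated
  near <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4000, 4100))
  a <- associate_peaks_to_genes(near, genes, flank = 1000)
  expect_equal(a$gene_id, "gA")
  expect_equal(a$gap_bp, 900)
  # gap exactly 1000 -> associated; 1001 -> not
  at_edge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3900, 4000))
  expect_equal(nrow(associate_peaks_to_genes(at_edge, genes)), 1)
  beyond <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 3999))
  expect_equal(nrow(associate_peaks_to_genes(beyond, genes)), 0)
  # peak inside the gene: gap 0
  inside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5500, 5600))
  expect_equal(associate_peaks_to_genes(inside, genes)$gap_bp, 0)
})

test_that("association tables are inverse images of each other", {
  gen <- generate_genome(2, 5e5, 60, seed = 17)
  set.seed(18)
  peaks <- random_granges(40, gen$genome, max_len = 2000)
  names(peaks) <- paste0("pk", seq_along(peaks))
  tab <- associate_peaks_to_genes(peaks, gen$genes)
  # every (peak, gene) pair appears once; rebuild the map both ways
  by_peak <- split(tab$gene_id, tab$peak_id)
  by_gene <- split(tab$peak_id, tab$gene_id)
  for (p in names(by_peak)) {
    for (g in by_peak[[p]]) expect_true(p %in% by_gene[[g]])
  }
})

test_that("feature classification counts non-exclusive categories", {
  # two genes 1.5 kb apart; a peak spanning gene A's body and gene B's
  # upstream flank counts in both
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1000, 4001),
                                                           c(2500, 6000)),
                                  strand = c("+", "+"))
  genes$gene_id <- c("gA", "gB")
  peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2400, 3500))
  cl <- classify_peak_features(peak, genes)
  counts <- stats::setNames(cl$count, cl$category)
  expect_equal(counts[["genes"]], 1L)
  expect_equal(counts[["upstream"]], 1L)
  expect_equal(counts[["intergenic"]], 0L)

  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20000, 21000))
  cf <- classify_peak_features(far, genes)
  expect_equal(stats::setNames(cf$count, cf$category)[["intergenic"]], 1L)

  # upstream is strand-aware: for a - strand gene it is to the right
  gm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 6000),
                               strand = "-")
  gm$gene_id <- "gC"
  right <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6100, 6200))
  cr <- classify_peak_features(right, gm)
  cc <- stats::setNames(cr$count, cr$category)
  expect_equal(cc[["upstream"]], 1L)
  expect_equal(cc[["downstream"]], 0L)
})

test_that("random peak sets preserve counts and lengths per chromosome", {
  genome <- genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
  set.seed(23)
  peaks <- GenomicRanges::GRanges(
    rep(c("chr1", "chr2"), c(10, 6)),
    IRanges::IRanges(c(sample.int(9e5, 10), sample.int(4e5, 6)),
                     width = c(sample(500:3000, 10), sample(200:1000, 6))),
    seqinfo = genome)
  peaks <- GenomicRanges::sort(peaks)
  rp <- random_peak_set(peaks, genome, seed = 5)
  for (chr in c("chr1", "chr2")) {
    o <- peaks[GenomicRanges::seqnames(peaks) == chr]
    r <- rp[GenomicRanges::seqnames(rp) == chr]
    expect_length(r, length(o))
    expect_equal(sort(IRanges::width(r)), sort(IRanges::width(o)))
  }
  expect_identical(GenomicRanges::start(random_peak_set(peaks, genome, seed = 5)),
                   GenomicRanges::start(rp))
  rd <- random_peak_set(peaks, genome, seed = 6, disjoint = TRUE)
  expect_true(IRanges::isDisjoint(rd))
  too_long <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 6e5))
  expect_error(random_peak_set(too_long, genome), "longer than")
})

test_that("random placement is uniform (mean-start check)", {
  genome <- genome_layout("chr1", 1e6)
  one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  set.seed(29)
  starts <- replicate(1000, GenomicRanges::start(random_peak_set(one, genome)))
  # uniform on [1, 999001]: mean 499501, sd range/sqrt(12)
  se <- (1e6 - 1000) / sqrt(12) / sqrt(1000)
  expect_lt(abs(mean(starts) - 499501), 3 * se)
})

test_that("peaks planted in upstream flanks are detected as enriched", {
  gen <- generate_genome(2, 1e6, 80, seed = 33)
  up <- suppressWarnings(GenomicRanges::flank(gen$genes, 1000, start = TRUE))
  up <- up[GenomicRanges::start(up) > 0][1:50]
  peaks <- GenomicRanges::reduce(
    GenomicRanges::trim(suppressWarnings(
      GenomicRanges::resize(up, 400, fix = "center"))),
    ignore.strand = TRUE)
  enr <- feature_enrichment(peaks, gen$genes, gen$genome, n_sim = 200, seed = 7)
  z_up <- enr$z_score[enr$category == "upstream"]
  expect_gt(z_up, 3)
  expect_equal(enr$empirical_p[enr$category == "upstream"], 1 / 201)
})

test_that("a feature covering the whole genome gives a degenerate null", {
  genome <- genome_layout("chr1", 1e5)
  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e5),
                                  strand = "+")
  whole$gene_id <- "gAll"
  set.seed(3)
  peaks <- random_granges(10, genome, max_len = 500)
  enr <- feature_enrichment(peaks, whole, genome, n_sim = 50, seed = 2)
  g <- enr[enr$category == "genes", ]
  expect_equal(g$observed_frequency, 1)
  expect_equal(g$null_sd, 0)
  expect_true(g$degenerate)
  expect_equal(g$z_score, 0)
  expect_true(all(enr$empirical_p >= 1 / 51))
})
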