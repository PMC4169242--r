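make_tracks <- function(...) {
  vals <- list(...)
  pos <- seq(150, by = 300, length.out = length(vals[[1]]))
  lapply(vals, function(v) make_probe_track(pos, v))
}

test_that("quantile normalization maps tracks to the mean order statistics", {
  tr <- make_tracks(c(1, 2, 3), c(4, 5, 6))
  out <- quantile_normalize(tr)
  expect_equal(out[[1]]$value, c(2.5, 3.5, 4.5))
  expect_equal(out[[2]]$value, c(2.5, 3.5, 4.5))

  single <- quantile_normalize(tr[1])
  expect_equal(single[[1]]$value, c(1, 2, 3))

  same <- make_tracks(c(3, 1, 2), c(3, 1, 2))
  expect_equal(quantile_normalize(same)[[1]]$value, c(3, 1, 2))
})

test_that("quantile normalization preserves within-track ranks", {
  set.seed(13)
  tr <- make_tracks(rnorm(500), rnorm(500, 1, 2), rnorm(500, -1, 0.5))
  out <- quantile_normalize(tr)
  for (i in 1:3) {
    expect_equal(stats::cor(tr[[i]]$value, out[[i]]$value,
                            method = "spearman"), 1)
    expect_equal(sort(out[[i]]$value), sort(out[[1]]$value))
  }
})

test_that("tracks on different probe maps are rejected", {
  a <- make_probe_track(c(100, 400), c(1, 2))
  b <- make_probe_track(c(100, 500), c(1, 2))
  expect_error(quantile_normalize(list(a, b)), "share one probe map")
  expect_error(subtract_mock(a, b), "share one probe map")
})

test_that("median centring shifts to median zero", {
  tr <- make_tracks(c(1, 2, 3))[[1]]
  expect_equal(median_center(tr)$value, c(-1, 0, 1))
  expect_equal(median_center(median_center(tr))$value, c(-1, 0, 1))
  set.seed(3)
  r <- make_tracks(rnorm(101, 5))[[1]]
  expect_equal(stats::median(median_center(r)$value), 0)
})

test_that("replicate pooling takes the per-probe median with even-count mean", {
  tr <- make_tracks(c(1, 0), c(2, 0), c(9, 0))
  expect_equal(pool_replicates(tr)$value, c(2, 0))
  expect_equal(pool_replicates(tr[1])$value, c(1, 0))
  expect_equal(pool_replicates(make_tracks(c(1, 5), c(3, 7)))$value, c(2, 6))
})

test_that("running median matches the shrink-at-edges hand example", {
  tr <- make_tracks(c(0, 10, 0, 10, 0))[[1]]
  expect_equal(smooth_running_median(tr, 3)$value, c(5, 0, 10, 0, 5))
  expect_equal(smooth_running_median(tr, 1)$value, tr$value)
  const <- make_tracks(rep(2, 7))[[1]]
  expect_equal(smooth_running_median(const, 5)$value, rep(2, 7))
  expect_error(smooth_running_median(tr, 2), "odd")
})

test_that("running median never crosses chromosome boundaries", {
  pm <- data.frame(chrom = rep(c("chr1", "chr2"), each = 3),
                   pos = rep(c(150, 450, 750), 2))
  class(pm) <- c("probe_map", "data.frame")
  tr <- signal_track(pm, c(0, 0, 0, 10, 10, 10))
  sm <- smooth_running_median(tr, 3)
  # chr2's high values must not bleed into chr1's last probe
  expect_equal(sm$value, c(0, 0, 0, 10, 10, 10))
})

test_that("running median is idempotent on piecewise-constant tracks", {
  v <- rep(c(0, 3, 0), times = c(6, 5, 6))
  tr <- make_tracks(v)[[1]]
  once <- smooth_running_median(tr, 3)
  twice <- smooth_running_median(once, 3)
  expect_equal(once$value, v)
  expect_equal(twice$value, once$value)
})

test_that("mock subtraction removes shared artifacts and is exact", {
  tr <- make_tracks(c(1, 2, 3), c(1, 1, 1))
  expect_equal(subtract_mock(tr[[1]], tr[[1]])$value, c(0, 0, 0))
  zero <- make_tracks(c(0, 0, 0))[[1]]
  expect_equal(subtract_mock(tr[[1]], zero)$value, tr[[1]]$value)

  genome <- genome_layout("chr1", 2e5)
  pm <- generate_probe_map(genome, 300)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20001, width = 3000))
  art <- GenomicRanges::GRanges("chr1", IRanges::IRanges(120001, width = 3000))
  sim <- generate_chip_tracks(pm, chip_sim_truth(
    peaks, amplitude = 2, noise_sd = 0.2, n_replicates = 3, seed = 21,
    artifact_peaks = art, artifact_amplitude = 1.5))
  proc <- process_chip_tracks(sim$chip, sim$mock, window = 3)
  probe_gr <- GenomicRanges::GRanges(pm$chrom, IRanges::IRanges(pm$pos, width = 1))
  in_art <- IRanges::overlapsAny(probe_gr, art)
  # the artifact amplitude (1.5) is removed to within noise
  expect_lt(abs(mean(proc$value[in_art])), 3 * 0.2)
  in_peak <- IRanges::overlapsAny(probe_gr, peaks)
  expect_gt(mean(proc$value[in_peak]), 1.5)
})

test_that("the noise-free pipeline returns exactly amplitude in peaks, 0 outside", {
  genome <- genome_layout(c("chr1", "chr2"), c(1e5, 1e5))
  pm <- generate_probe_map(genome, 300)
  peaks <- GenomicRanges::GRanges(c("chr1", "chr2"),
                                  IRanges::IRanges(c(30001, 60001), width = 2500),
                                  seqinfo = genome)
  sim <- generate_chip_tracks(pm, chip_sim_truth(peaks, amplitude = 2,
                                                 noise_sd = 0, n_replicates = 3,
                                                 seed = 1))
  proc <- process_chip_tracks(sim$chip, sim$mock, window = 3)
  probe_gr <- GenomicRanges::GRanges(pm$chrom, IRanges::IRanges(pm$pos, width = 1))
  inside <- IRanges::overlapsAny(probe_gr, peaks)
  expect_true(all(proc$value[inside] == 2))
  expect_true(all(proc$value[!inside] == 0))
})

test_that("bedGraph tracks round-trip", {
  genome <- genome_layout("chr1", 1e4)
  pm <- generate_probe_map(genome, 300)
  tr <- signal_track(pm, round(rnorm(nrow(pm)), 4), "t")
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f)
  expect_equal(back$probes$pos, tr$probes$pos)
  expect_equal(back$value, tr$value)
})
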