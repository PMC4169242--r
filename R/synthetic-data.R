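#' Generate a synthetic genome with non-overlapping gene models
#'
#' Places `n_genes` genes of uniformly drawn length on a multi-chromosome
#' genome by rejection sampling (uniform start, chromosome picked with
#' probability proportional to its length, random strand), so that gene
#' bodies never overlap. Deterministic given `seed`.
#'
#' @param n_chrom Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Number of genes to place.
#' @param gene_length_range Two-element vector: min and max gene length (bp).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget per gene before giving up.
#' @return A list with `genome` (a `Seqinfo`) and `genes` (a sorted `GRanges`
#'   with `gene_id` column and random strand).
#' @export
generate_genome <- function(n_chrom = 2, chrom_length = 1e6, n_genes = 100,
                            gene_length_range = c(1000, 5000), seed = 1,
                            max_tries = 1000) {
  stopifnot(n_chrom >= 1, chrom_length > 0, n_genes >= 0,
            length(gene_length_range) == 2,
            gene_length_range[1] <= gene_length_range[2],
            gene_length_range[2] <= chrom_length)
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  genome <- genome_layout(chroms, rep(chrom_length, n_chrom))
  if (n_genes == 0) {
    genes <- GenomicRanges::GRanges(seqinfo = genome)
    genes$gene_id <- character(0)
    return(list(genome = genome, genes = genes))
  }
  occupied <- lapply(chroms, function(x) IRanges::IRanges())
  names(occupied) <- chroms
  chr_out <- character(n_genes); start_out <- integer(n_genes)
  width_out <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      len <- sample(gene_length_range[1]:gene_length_range[2], 1)
      chr <- sample(chroms, 1)
      start <- sample.int(chrom_length - len + 1, 1)
      cand <- IRanges::IRanges(start, width = len)
      if (!IRanges::overlapsAny(cand, occupied[[chr]])) {
        occupied[[chr]] <- c(occupied[[chr]], cand)
        chr_out[i] <- chr; start_out[i] <- start; width_out[i] <- len
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place ", n_genes, " non-overlapping genes; ",
                      "genome too crowded")
  }
  genes <- GenomicRanges::GRanges(
    chr_out, IRanges::IRanges(start_out, width = width_out),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    seqinfo = genome
  )
  genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)
  genes$gene_id <- sprintf("g%04d", seq_len(n_genes))
  list(genome = genome, genes = genes)
}

#' Generate a tiling-array probe map
#'
#' Probe centres are laid out on a deterministic grid at `spacing/2 + k *
#' spacing` along each chromosome, with optional Gaussian jitter (clipped to
#' `spacing/2 - 1` so that centres stay strictly increasing). This emulates a
#' whole-genome tiling array with probes spaced approximately every
#' `spacing` bp.
#'
#' @param genome A `Seqinfo` from [genome_layout()].
#' @param spacing Nominal centre-to-centre distance (bp); default 300.
#' @param jitter_sd Standard deviation of the placement jitter (bp).
#' @param seed Integer seed (only consumed when `jitter_sd > 0`).
#' @return A `probe_map`: a data.frame with columns `chrom` and `pos`
#'   (strictly increasing within each chromosome), chromosomes in `Seqinfo`
#'   order.
#' @export
generate_probe_map <- function(genome, spacing = 300, jitter_sd = 0, seed = 1) {
  stopifnot(spacing > 0, jitter_sd >= 0)
  if (jitter_sd > 0) set.seed(seed)
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- GenomeInfoDb::seqlengths(genome)
  parts <- lapply(chroms, function(chr) {
    len <- lens[[chr]]
    centers <- seq(floor(spacing / 2), len - ceiling(spacing / 2), by = spacing)
    if (jitter_sd > 0) {
      jit <- round(stats::rnorm(length(centers), 0, jitter_sd))
      lim <- floor(spacing / 2) - 1
      jit <- pmin(pmax(jit, -lim), lim)
      centers <- centers + jit
    }
    data.frame(chrom = chr, pos = as.integer(centers))
  })
  pm <- do.call(rbind, parts)
  class(pm) <- c("probe_map", "data.frame")
  attr(pm, "genome") <- genome
  pm
}

#' Bundle the ground truth of a ChIP-chip simulation
#'
#' @param planted_peaks `GRanges` of truly enriched regions.
#' @param amplitude Log2-ratio enrichment added to probes inside a planted
#'   peak; must be > 0.
#' @param noise_sd Gaussian probe noise (log2-ratio units).
#' @param n_replicates Number of biological replicates to simulate.
#' @param seed Integer seed.
#' @param artifact_peaks Optional `GRanges` of nonspecific regions enriched in
#'   both the ChIP and the mock tracks (removed by mock subtraction).
#' @param artifact_amplitude Enrichment of the artifact regions.
#' @param scale_factors Optional per-replicate multiplicative scale applied to
#'   the whole track, to exercise quantile normalization; default all 1.
#' @return A list of class `chip_sim_truth`.
#' @export
chip_sim_truth <- function(planted_peaks, amplitude = 2, noise_sd = 0.3,
                           n_replicates = 3, seed = 1, artifact_peaks = NULL,
                           artifact_amplitude = 1, scale_factors = NULL) {
  stopifnot(amplitude > 0, noise_sd >= 0, n_replicates >= 1)
  if (is.null(scale_factors)) scale_factors <- rep(1, n_replicates)
  stopifnot(length(scale_factors) == n_replicates, all(scale_factors > 0))
  structure(
    list(planted_peaks = planted_peaks, amplitude = amplitude,
         noise_sd = noise_sd, n_replicates = n_replicates, seed = seed,
         artifact_peaks = artifact_peaks,
         artifact_amplitude = artifact_amplitude,
         scale_factors = scale_factors),
    class = "chip_sim_truth"
  )
}

#' Plant peaks uniformly in a genome
#'
#' Convenience generator for simulation truth: disjoint peaks of uniform
#' random length placed uniformly (rejection sampling against overlap).
#'
#' @param genome A `Seqinfo`.
#' @param n_peaks Number of peaks.
#' @param length_range Min/max peak length (bp).
#' @param seed Integer seed.
#' @return A sorted disjoint `GRanges`.
#' @export
plant_peaks <- function(genome, n_peaks = 50, length_range = c(1000, 3000),
                        seed = 1) {
  set.seed(seed)
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- GenomeInfoDb::seqlengths(genome)
  occupied <- lapply(chroms, function(x) IRanges::IRanges())
  names(occupied) <- chroms
  chr_out <- character(n_peaks); start_out <- integer(n_peaks)
  width_out <- integer(n_peaks)
  for (i in seq_len(n_peaks)) {
    repeat {
      len <- sample(length_range[1]:length_range[2], 1)
      chr <- sample(chroms, 1)
      start <- sample.int(lens[[chr]] - len + 1, 1)
      cand <- IRanges::IRanges(start, width = len)
      # keep planted peaks separated by > 1 kb so truth regions stay distinct
      if (!IRanges::overlapsAny(cand + 1000, occupied[[chr]])) {
        occupied[[chr]] <- c(occupied[[chr]], cand)
        chr_out[i] <- chr; start_out[i] <- start; width_out[i] <- len
        break
      }
    }
  }
  gr <- GenomicRanges::GRanges(chr_out,
                               IRanges::IRanges(start_out, width = width_out),
                               seqinfo = genome)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Simulate ChIP and mock signal tracks over a probe map
#'
#' Each replicate track carries `amplitude` at probes inside a planted peak
#' plus independent Gaussian noise; the mock track is pure noise plus any
#' shared artifact regions. All tracks share the probe map. Deterministic
#' given the truth's seed.
#'
#' @param probes A `probe_map` from [generate_probe_map()].
#' @param truth A [chip_sim_truth()] object.
#' @return A list with `chip` (list of `signal_track`, one per replicate),
#'   `mock` (a single `signal_track`), and `truth`.
#' @export
generate_chip_tracks <- function(probes, truth) {
  stopifnot(inherits(truth, "chip_sim_truth"))
  set.seed(truth$seed)
  n <- nrow(probes)
  probe_gr <- GenomicRanges::GRanges(probes$chrom,
                                     IRanges::IRanges(probes$pos, width = 1))
  in_peak <- IRanges::overlapsAny(probe_gr, truth$planted_peaks,
                                  ignore.strand = TRUE)
  in_artifact <- if (is.null(truth$artifact_peaks)) rep(FALSE, n) else
    IRanges::overlapsAny(probe_gr, truth$artifact_peaks, ignore.strand = TRUE)
  base <- truth$amplitude * in_peak + truth$artifact_amplitude * in_artifact
  chip <- lapply(seq_len(truth$n_replicates), function(r) {
    v <- truth$scale_factors[r] *
      (base + stats::rnorm(n, 0, truth$noise_sd))
    signal_track(probes, v, label = paste0("chip_rep", r))
  })
  mock_v <- truth$artifact_amplitude * in_artifact +
    stats::rnorm(n, 0, truth$noise_sd)
  list(chip = chip,
       mock = signal_track(probes, mock_v, label = "mock"),
       truth = truth)
}

#' Bundle the ground truth of an expression simulation
#'
#' @param gene_ids Character vector of all gene ids.
#' @param de_gene_ids Subset of `gene_ids` carrying a planted effect.
#' @param effect_log2 Planted log2 fold change (scalar, or one per DE gene).
#' @param noise_sd Per-observation Gaussian noise SD (log2 units).
#' @param batch_sd SD of the shared batch offsets.
#' @param n_per_group Samples per condition (>= 2).
#' @param seed Integer seed.
#' @return A list of class `expr_sim_truth`.
#' @export
expr_sim_truth <- function(gene_ids, de_gene_ids = character(0),
                           effect_log2 = 1, noise_sd = 0.25, batch_sd = 0,
                           n_per_group = 4, seed = 1) {
  stopifnot(all(de_gene_ids %in% gene_ids), n_per_group >= 2,
            noise_sd >= 0, batch_sd >= 0)
  if (length(effect_log2) == 1) {
    effect_log2 <- rep(effect_log2, length(de_gene_ids))
  }
  stopifnot(length(effect_log2) == length(de_gene_ids))
  structure(
    list(gene_ids = gene_ids, de_gene_ids = de_gene_ids,
         effect_log2 = effect_log2, noise_sd = noise_sd, batch_sd = batch_sd,
         n_per_group = n_per_group, seed = seed),
    class = "expr_sim_truth"
  )
}

#' Simulate a two-condition expression matrix with batch structure
#'
#' Emulates an induced-vs-control microarray design processed in dissection
#' batches: each batch contains one control and one induced sample and
#' carries a shared Gaussian offset. Values are
#' `baseline(g) + effect * [g DE & sample induced] + batch(sample) + noise`.
#'
#' @param truth An [expr_sim_truth()] object.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log2
#'   intensity (defaults emulate typical log2 microarray intensities).
#' @return A list with `expr` (genes x samples numeric matrix), `design`
#'   (data.frame: `sample`, `condition` in {control, induced}, `batch`), and
#'   `truth`.
#' @export
generate_expression <- function(truth, baseline_mean = 8, baseline_sd = 1.5) {
  stopifnot(inherits(truth, "expr_sim_truth"))
  set.seed(truth$seed)
  g <- length(truth$gene_ids)
  n <- 2 * truth$n_per_group
  condition <- rep(c("control", "induced"), each = truth$n_per_group)
  batch <- paste0("b", rep(seq_len(truth$n_per_group), times = 2))
  samples <- paste0("s", seq_len(n))
  baseline <- stats::rnorm(g, baseline_mean, baseline_sd)
  batch_eff <- stats::rnorm(truth$n_per_group, 0, truth$batch_sd)
  names(batch_eff) <- paste0("b", seq_len(truth$n_per_group))
  effect <- numeric(g)
  effect[match(truth$de_gene_ids, truth$gene_ids)] <- truth$effect_log2
  m <- matrix(stats::rnorm(g * n, 0, truth$noise_sd), g, n)
  m <- m + baseline +
    outer(effect, as.numeric(condition == "induced")) +
    matrix(batch_eff[batch], g, n, byrow = TRUE)
  dimnames(m) <- list(truth$gene_ids, samples)
  design <- data.frame(sample = samples, condition = condition, batch = batch,
                       stringsAsFactors = FALSE)
  list(expr = m, design = design, truth = truth)
}
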