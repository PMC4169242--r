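#' Derive independent child seeds from one global seed
#'
#' Stages of a pipeline each get their own RNG seed so that any stage can be
#' rerun in isolation and reproduce its part of a run. Child seeds are the
#' first `n` draws of `sample.int(2^31 - 1)` under the global seed.
#'
#' @param seed Global integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read an expression matrix and design table
#'
#' @param expr_path TSV with gene ids in the first column, one column per
#'   sample.
#' @param design_path TSV with columns `sample`, `condition`, and optionally
#'   `batch`.
#' @return A list with `expr` (matrix) and `design` (data.frame).
#' @export
read_expression <- function(expr_path, design_path) {
  tab <- .read_tsv(expr_path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  design <- .read_tsv(design_path)
  if (!all(colnames(m) %in% design$sample)) {
    stop("design table must describe every sample column")
  }
  list(expr = m, design = design)
}

#' Write an expression matrix and design table
#'
#' @param expr Genes x samples matrix.
#' @param design Design data.frame.
#' @param expr_path,design_path Output paths.
#' @return `expr_path`, invisibly.
#' @export
write_expression <- function(expr, design, expr_path, design_path) {
  .write_tsv(cbind(data.frame(gene_id = rownames(expr)),
                   as.data.frame(expr)), expr_path)
  .write_tsv(design, design_path)
  invisible(expr_path)
}

.manifest <- function(out_dir, stage, params, seed, artifacts) {
  manifest <- file.path(out_dir, "run_manifest.yaml")
  entry <- list(list(
    stage = stage,
    seed = seed,
    params = params,
    artifacts = lapply(artifacts, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  ))
  cat(yaml::as.yaml(entry), file = manifest, append = TRUE)
  invisible(manifest)
}

#' Run the ChIP-chip arm of the pipeline
#'
#' Normalize, pool, smooth, mock-subtract, call peaks, associate them with
#' genes, and test feature enrichment; write peaks BED, association TSV,
#' enrichment TSV, and a run manifest with artifact checksums.
#'
#' @param chip List of replicate `signal_track`s (or bedGraph paths).
#' @param mock A mock `signal_track` (or bedGraph path), or NULL.
#' @param genes `GRanges` gene annotation (or GFF3 path).
#' @param genome `Seqinfo`.
#' @param out_dir Output directory (created if needed).
#' @param window,threshold,max_gap,min_probes,flank,subtract_first Stage
#'   parameters; see [process_chip_tracks()], [call_peaks()],
#'   [associate_peaks_to_genes()].
#' @param n_sim Random peak sets for enrichment; default 1000.
#' @param seed Global seed for the enrichment null.
#' @return A list with `peaks`, `association`, `enrichment` and the artifact
#'   paths.
#' @export
run_chip_pipeline <- function(chip, mock, genes, genome, out_dir,
                              window = 3, threshold = 0.97, max_gap = 600,
                              min_probes = 3, flank = 1000, n_sim = 1000,
                              subtract_first = FALSE, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(chip)) chip <- lapply(chip, read_bedgraph)
  if (is.character(mock)) mock <- read_bedgraph(mock)
  if (is.character(genes)) genes <- read_gff3(genes, genome)
  processed <- process_chip_tracks(chip, mock, window = window,
                                   subtract_first = subtract_first)
  peaks <- call_peaks(processed, threshold = threshold, max_gap = max_gap,
                      min_probes = min_probes, genome = genome)
  assoc <- associate_peaks_to_genes(peaks, genes, flank = flank)
  enr <- feature_enrichment(peaks, genes, genome, n_sim = n_sim, seed = seed,
                            flank = flank)
  paths <- c(peaks = file.path(out_dir, "peaks.bed"),
             association = file.path(out_dir, "peak_gene_association.tsv"),
             enrichment = file.path(out_dir, "feature_enrichment.tsv"))
  write_bed(peaks, paths["peaks"])
  .write_tsv(assoc, paths["association"])
  .write_tsv(as.data.frame(enr), paths["enrichment"])
  .manifest(out_dir, "chip",
            list(window = window, threshold = threshold, max_gap = max_gap,
                 min_probes = min_probes, flank = flank, n_sim = n_sim),
            seed, as.list(paths))
  list(peaks = peaks, association = assoc, enrichment = enr, paths = paths)
}

#' Run the factor-overlap arm of the pipeline
#'
#' Given two factors' peak sets and a gene annotation: directional
#' peak-overlap counts and fractions, hypergeometric overlap of the
#' associated gene sets (universe = all annotated genes), and the
#' block-bootstrap significance of the basepair overlap.
#'
#' @param peaks_a,peaks_b `GRanges` peak sets (or BED paths).
#' @param genes `GRanges` annotation (or GFF3 path).
#' @param genome `Seqinfo`.
#' @param out_dir Output directory.
#' @param flank Gene-association flank; default 1000.
#' @param n_iterations,block_length Bootstrap parameters.
#' @param seed Integer seed.
#' @return A list with `peak_overlap`, `gene_overlap`, `bootstrap`, `paths`.
#' @export
run_overlap_pipeline <- function(peaks_a, peaks_b, genes, genome, out_dir,
                                 flank = 1000, n_iterations = 10000,
                                 block_length = 100000, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(peaks_a)) peaks_a <- read_bed(peaks_a, genome)
  if (is.character(peaks_b)) peaks_b <- read_bed(peaks_b, genome)
  if (is.character(genes)) genes <- read_gff3(genes, genome)
  counts <- directional_peak_overlap_counts(peaks_a, peaks_b)
  genes_a <- unique(associate_peaks_to_genes(peaks_a, genes, flank)$gene_id)
  genes_b <- unique(associate_peaks_to_genes(peaks_b, genes, flank)$gene_id)
  hyper <- gene_overlap_hypergeom(genes_a, genes_b, genes$gene_id)
  boot <- block_bootstrap_overlap(peaks_a, peaks_b, genome,
                                  n_iterations = n_iterations,
                                  block_length = block_length, seed = seed)
  report <- data.frame(
    statistic = c("peaks_a_overlapping_b", "peaks_b_overlapping_a",
                  "mean_overlap_count", "frac_a", "frac_b",
                  "shared_genes", "gene_overlap_p",
                  "observed_bp", "bootstrap_z", "bootstrap_p"),
    value = c(counts$count_a, counts$count_b, counts$mean, counts$frac_a,
              counts$frac_b, hyper$overlap, hyper$p, boot$observed,
              boot$z_score, boot$p_empirical)
  )
  path <- file.path(out_dir, "overlap_report.tsv")
  .write_tsv(report, path)
  .manifest(out_dir, "overlap",
            list(flank = flank, n_iterations = n_iterations,
                 block_length = block_length), seed, list(path))
  list(peak_overlap = counts, gene_overlap = hyper, bootstrap = boot,
       paths = c(report = path))
}

#' Run the differential-expression arm of the pipeline
#'
#' Presence filtering, per-gene OLS with batch covariate, BH selection, and
#' (optionally) the hypergeometric enrichment of bound genes among the
#' selected genes.
#'
#' @param expr Genes x samples matrix (or TSV path).
#' @param design Design data.frame (or TSV path when `expr` is a path).
#' @param out_dir Output directory.
#' @param q Target FDR; default 0.05.
#' @param min_present Presence-filter sample count; default 4.
#' @param intensity_floor Presence-filter floor; default matrix 25th
#'   percentile.
#' @param bound_genes Optional character vector of peak-associated gene ids.
#' @return A list with `de` (selected `de_result`), `p_cutoff`,
#'   `n_selected`, optional `bound_enrichment`, and `paths`.
#' @export
run_de_pipeline <- function(expr, design, out_dir, q = 0.05, min_present = 4,
                            intensity_floor = NULL, bound_genes = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(expr)) {
    io <- read_expression(expr, design)
    expr <- io$expr; design <- io$design
  }
  if (is.null(intensity_floor)) intensity_floor <- stats::quantile(expr, 0.25)
  kept <- presence_filter(expr, min_present, intensity_floor)
  de <- select_de(fit_de(kept, design), q = q)
  path <- file.path(out_dir, "de_results.tsv")
  .write_tsv(as.data.frame(de), path)
  out <- list(de = de, p_cutoff = attr(de, "p_cutoff"),
              n_selected = attr(de, "n_selected"), paths = c(de = path))
  if (!is.null(bound_genes)) {
    out$bound_enrichment <- de_bound_enrichment(
      de$gene_id[de$selected], intersect(bound_genes, de$gene_id), de$gene_id)
  }
  .manifest(out_dir, "de",
            list(q = q, min_present = min_present,
                 intensity_floor = unname(intensity_floor)),
            NA, list(path))
  out
}

#' Run the Boolean-model arm of the pipeline
#'
#' Exact probabilities for each model under each clamping scenario, with an
#' optional Monte-Carlo cross-check column per scenario.
#'
#' @param out_dir Output directory.
#' @param models,scenarios,n_transitions As in [compare_models()].
#' @param mc_runs Monte-Carlo sample size for the cross-check column; 0
#'   disables it.
#' @param seed Seed for the Monte-Carlo draws.
#' @return A list with `table` (the comparison data.frame) and `paths`.
#' @export
run_boolnet_pipeline <- function(out_dir,
                                 models = list(
                                   feedforward = build_feedforward_model(),
                                   linear = build_linear_model()),
                                 scenarios = list(dFOXO = c(dFOXO = 1),
                                                  PNT = c(PNT = 1),
                                                  both = c(dFOXO = 1, PNT = 1)),
                                 n_transitions = 1000, mc_runs = 0, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- compare_models(models, scenarios, n_transitions)
  if (mc_runs > 0) {
    for (sc in names(scenarios)) {
      tab[[paste0(sc, "_mc")]] <- vapply(models, function(m) {
        simulate_probability(m, clamps = scenarios[[sc]],
                             n_transitions = n_transitions,
                             mode = "monte_carlo", n_runs = mc_runs,
                             seed = seed)$probability_target_active
      }, numeric(1))
    }
  }
  path <- file.path(out_dir, "boolnet_probabilities.tsv")
  .write_tsv(tab, path)
  .manifest(out_dir, "boolnet",
            list(n_transitions = n_transitions, mc_runs = mc_runs),
            seed, list(path))
  list(table = tab, paths = c(table = path))
}

#' Run the bundled synthetic end-to-end demonstration
#'
#' Generates a small synthetic study — genome, genes, probe map, planted-peak
#' ChIP/mock tracks, and an expression matrix with planted fold changes —
#' then runs all pipeline arms: peak calling with annotation and feature
#' enrichment, overlap of the called peaks against the planted truth,
#' differential expression, the binding/expression enrichment join, and the
#' Boolean model comparison. All randomness derives from `seed`, so two runs
#' with the same seed produce byte-identical artifacts.
#'
#' @param out_dir Output directory.
#' @param seed Global seed; default 1.
#' @param n_sim Random peak sets in the enrichment stage (kept modest so the
#'   demo stays fast).
#' @param n_iterations Bootstrap iterations in the overlap stage.
#' @return A list with the per-arm results and `out_dir`.
#' @export
run_demo <- function(out_dir, seed = 1, n_sim = 200, n_iterations = 500) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(out_dir, "run_manifest.yaml")
  if (file.exists(manifest)) file.remove(manifest)
  seeds <- derive_seeds(seed, 6)
  gen <- generate_genome(n_chrom = 2, chrom_length = 2e6, n_genes = 120,
                         seed = seeds[1])
  probes <- generate_probe_map(gen$genome, spacing = 300, jitter_sd = 30,
                               seed = seeds[2])
  truth_peaks <- plant_peaks(gen$genome, n_peaks = 30,
                             length_range = c(1000, 3000), seed = seeds[3])
  sim <- generate_chip_tracks(probes, chip_sim_truth(
    truth_peaks, amplitude = 2, noise_sd = 0.3, n_replicates = 3,
    seed = seeds[3]))
  write_gff3(gen$genes, file.path(out_dir, "genes.gff3"))
  write_bed(truth_peaks, file.path(out_dir, "planted_peaks.bed"))
  for (i in seq_along(sim$chip)) {
    write_bedgraph(sim$chip[[i]], file.path(out_dir,
                                            sprintf("chip_rep%d.bedgraph", i)))
  }
  write_bedgraph(sim$mock, file.path(out_dir, "mock.bedgraph"))
  chip_res <- run_chip_pipeline(sim$chip, sim$mock, gen$genes, gen$genome,
                                out_dir, n_sim = n_sim, seed = seeds[4])
  overlap_res <- run_overlap_pipeline(chip_res$peaks, truth_peaks, gen$genes,
                                      gen$genome, out_dir,
                                      n_iterations = n_iterations,
                                      block_length = 1e5, seed = seeds[5])
  gene_ids <- gen$genes$gene_id
  bound <- unique(chip_res$association$gene_id)
  de_targets <- intersect(gene_ids, bound)
  n_de <- max(5, length(de_targets) %/% 2)
  etruth <- expr_sim_truth(gene_ids,
                           de_gene_ids = utils::head(de_targets, n_de),
                           effect_log2 = 1, noise_sd = 0.25, batch_sd = 0.5,
                           n_per_group = 4, seed = seeds[6])
  esim <- generate_expression(etruth)
  write_expression(esim$expr, esim$design,
                   file.path(out_dir, "expression.tsv"),
                   file.path(out_dir, "design.tsv"))
  de_res <- run_de_pipeline(esim$expr, esim$design, out_dir, q = 0.05,
                            min_present = 4, bound_genes = bound)
  bool_res <- run_boolnet_pipeline(out_dir, mc_runs = 2000, seed = seeds[6])
  list(chip = chip_res, overlap = overlap_res, de = de_res,
       boolnet = bool_res, out_dir = out_dir)
}
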