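#' Associate peaks with nearby genes
#'
#' A gene is associated with a peak when any part of the gene lies within
#' `flank` bp of the peak (gap 0 for overlap, otherwise the basepair distance
#' between the nearest interval boundaries). Association is strand-agnostic
#' and many-to-many: one peak can hit several genes and vice versa.
#'
#' @param peaks `GRanges` peak set.
#' @param genes `GRanges` with a `gene_id` column.
#' @param flank Maximum gap in bp; default 1000 (the classic "within 1 kb"
#'   rule).
#' @return A data.frame with columns `peak_id` (name, or `peak_<i>` by
#'   position), `gene_id`, `gap_bp`.
#' @export
associate_peaks_to_genes <- function(peaks, genes, flank = 1000) {
  stopifnot(!is.null(genes$gene_id))
  hits <- GenomicRanges::findOverlaps(peaks, genes, maxgap = flank,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ids <- names(peaks)
  if (is.null(ids)) ids <- paste0("peak_", seq_along(peaks))
  data.frame(
    peak_id = ids[qi],
    gene_id = genes$gene_id[si],
    gap_bp = GenomicRanges::distance(peaks[qi], genes[si],
                                     ignore.strand = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Genomic feature categories of a gene annotation
#'
#' Precomputes the reduced interval sets for the four feature categories used
#' in peak classification: gene bodies, strand-aware 1 kb upstream flanks,
#' strand-aware 1 kb downstream flanks (each trimmed at chromosome ends when
#' a genome is attached), and everything else (intergenic).
#'
#' @param genes `GRanges` of gene bodies with strand.
#' @param flank Flank size in bp.
#' @return A named list of reduced `GRanges`: `upstream`, `downstream`,
#'   `genes`.
#' @export
feature_categories <- function(genes, flank = 1000) {
  # flanks of genes near chromosome ends run out of bounds before trimming
  up <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::flank(genes, flank, start = TRUE)))
  down <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::flank(genes, flank, start = FALSE)))
  list(
    upstream = GenomicRanges::reduce(up, ignore.strand = TRUE),
    downstream = GenomicRanges::reduce(down, ignore.strand = TRUE),
    genes = GenomicRanges::reduce(genes, ignore.strand = TRUE)
  )
}

#' Classify peaks by genomic feature
#'
#' Each peak counts toward every category it intersects: `upstream` and
#' `downstream` (within `flank` bp of a gene start/end, strand-aware),
#' `genes` (overlapping an annotated gene body), and `intergenic` (touching
#' none of the above). Categories are not mutually exclusive, so counts can
#' sum to more than the number of peaks.
#'
#' @param peaks `GRanges` peak set.
#' @param genes `GRanges` of genes, or a precomputed [feature_categories()]
#'   list.
#' @param flank Flank size in bp; default 1000.
#' @return A data.frame with one row per category: `category`, `count`,
#'   `frequency` (fraction of peaks).
#' @export
classify_peak_features <- function(peaks, genes, flank = 1000) {
  cats <- if (is.list(genes) && !methods::is(genes, "GRanges")) genes else
    feature_categories(genes, flank)
  hit <- vapply(cats, function(f) {
    IRanges::overlapsAny(peaks, f, ignore.strand = TRUE)
  }, logical(length(peaks)))
  if (length(peaks) == 1) hit <- matrix(hit, nrow = 1,
                                        dimnames = list(NULL, names(cats)))
  inter <- if (length(peaks)) rowSums(hit) == 0 else logical(0)
  counts <- c(colSums(hit), intergenic = sum(inter))
  data.frame(
    category = names(counts),
    count = as.integer(counts),
    frequency = if (length(peaks)) as.numeric(counts) / length(peaks) else
      rep(NA_real_, length(counts)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Draw a random peak set preserving size, length and chromosomal distribution
#'
#' Produces a peak set with the identical number of peaks per chromosome and
#' the identical multiset of lengths per chromosome as the input, but with
#' starts placed uniformly along each chromosome. Randomly placed intervals
#' may overlap one another (the null preserves marginal placement, not
#' disjointness); `disjoint = TRUE` switches to bounded rejection sampling.
#'
#' Uses the current RNG state; call `set.seed()` (or pass `seed`) for
#' reproducibility.
#'
#' @param peaks `GRanges` template peak set.
#' @param genome `Seqinfo` giving chromosome lengths.
#' @param seed Optional integer seed.
#' @param disjoint Require the randomized peaks to be non-overlapping.
#' @param max_tries Rejection budget per peak in disjoint mode.
#' @return A `GRanges` with the same per-chromosome counts and lengths.
#' @export
random_peak_set <- function(peaks, genome, seed = NULL, disjoint = FALSE,
                            max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  lens <- GenomeInfoDb::seqlengths(genome)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  w <- IRanges::width(peaks)
  if (any(w > lens[chrom])) stop("peak longer than its chromosome")
  max_start <- lens[chrom] - w + 1
  if (!disjoint) {
    start <- as.integer(floor(stats::runif(length(peaks)) * max_start)) + 1L
  } else {
    start <- integer(length(peaks))
    occ <- lapply(names(lens), function(x) IRanges::IRanges())
    names(occ) <- names(lens)
    for (i in seq_along(peaks)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        s <- sample.int(max_start[i], 1)
        cand <- IRanges::IRanges(s, width = w[i])
        if (!IRanges::overlapsAny(cand, occ[[chrom[i]]])) {
          occ[[chrom[i]]] <- c(occ[[chrom[i]]], cand)
          start[i] <- s
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place disjoint random peaks")
    }
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = w),
                               seqinfo = genome)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Feature enrichment of a peak set against a random-placement null
#'
#' Compares the observed frequency of peaks hitting each feature category
#' with the distribution over `n_sim` random peak sets of identical size,
#' length and chromosomal distribution. For each category it reports the
#' Z-score `(obs - null_mean)/null_sd` and an empirical p-value
#' `(1 + #{as-or-more-extreme}) / (n_sim + 1)`, one-sided in the direction of
#' the observed deviation; the p-value can therefore never be reported as 0
#' (its floor is `1/(n_sim+1)`).
#'
#' @param peaks `GRanges` peak set.
#' @param genes `GRanges` gene annotation.
#' @param genome `Seqinfo`.
#' @param n_sim Number of random peak sets; default 1000.
#' @param seed Integer seed.
#' @param flank Flank size in bp; default 1000.
#' @return A data.frame of class `enrichment_result`, one row per category:
#'   `category`, `observed_frequency`, `null_mean`, `null_sd`, `z_score`,
#'   `empirical_p`, `degenerate`, `n_sim`. `degenerate` flags categories with
#'   `null_sd == 0`, whose z is reported as 0.
#' @export
feature_enrichment <- function(peaks, genes, genome, n_sim = 1000, seed = 1,
                               flank = 1000) {
  stopifnot(n_sim >= 2)
  set.seed(seed)
  cats <- feature_categories(genes, flank)
  obs <- classify_peak_features(peaks, cats)
  # all n_sim random peak sets drawn at once (same placement law as
  # random_peak_set: identical per-chromosome counts and lengths, uniform
  # starts) and classified with one overlap query per category
  lens <- GenomeInfoDb::seqlengths(genome)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  w <- IRanges::width(peaks)
  if (any(w > lens[chrom])) stop("peak longer than its chromosome")
  n <- length(peaks)
  max_start <- rep(lens[chrom] - w + 1, n_sim)
  starts <- as.integer(floor(stats::runif(n * n_sim) * max_start)) + 1L
  all_gr <- GenomicRanges::GRanges(rep(chrom, n_sim),
                                   IRanges::IRanges(starts, width = rep(w, n_sim)),
                                   seqinfo = genome)
  hit <- vapply(cats, function(f) {
    IRanges::overlapsAny(all_gr, f, ignore.strand = TRUE)
  }, logical(n * n_sim))
  hit <- cbind(hit, intergenic = rowSums(hit) == 0)
  null_freq <- vapply(colnames(hit), function(cat) {
    colSums(matrix(hit[, cat], nrow = n, ncol = n_sim)) / n
  }, numeric(n_sim))
  null_mean <- colMeans(null_freq)
  null_sd <- apply(null_freq, 2, stats::sd)
  degenerate <- null_sd == 0
  z <- ifelse(degenerate, 0, (obs$frequency - null_mean) / null_sd)
  emp_p <- vapply(seq_len(nrow(obs)), function(j) {
    extreme <- if (obs$frequency[j] >= null_mean[j]) {
      sum(null_freq[, j] >= obs$frequency[j])
    } else {
      sum(null_freq[, j] <= obs$frequency[j])
    }
    (1 + extreme) / (n_sim + 1)
  }, numeric(1))
  res <- data.frame(
    category = obs$category,
    observed_frequency = obs$frequency,
    null_mean = null_mean,
    null_sd = null_sd,
    z_score = z,
    empirical_p = emp_p,
    degenerate = degenerate,
    n_sim = n_sim,
    stringsAsFactors = FALSE
  )
  class(res) <- c("enrichment_result", "data.frame")
  res
}
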