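#' Call peaks on a processed signal track
#'
#' Threshold-and-merge peak calling on a smoothed, replicate-pooled,
#' mock-subtracted log2 enrichment track. A probe qualifies when its value is
#' at or above the threshold (in `absolute` mode the threshold is a signal
#' value, the classic y0 cutoff of 0.97; in `quantile` mode it is the given
#' quantile of all probe values). A peak is a maximal run of consecutive
#' qualifying probes on one chromosome — broken by any intervening
#' non-qualifying probe, or wherever the centre-to-centre distance between
#' consecutive qualifying probes exceeds `max_gap` — containing at least
#' `min_probes` probes. The peak interval spans the first through last probe
#' centre; its score is the maximum probe value in the run.
#'
#' @param track A `signal_track`.
#' @param threshold Signal threshold (default 0.97) or, in quantile mode, a
#'   probability in (0,1).
#' @param max_gap Maximum centre-to-centre distance (bp) between consecutive
#'   probes of one peak; default 600.
#' @param min_probes Minimum probes per peak; default 3.
#' @param mode `"absolute"` (default) or `"quantile"`.
#' @param genome Optional `Seqinfo` attached to the result.
#' @return A sorted `GRanges` with `score` (max probe value) and
#'   `probe_count` columns. Empty track gives an empty peak set.
#' @export
call_peaks <- function(track, threshold = 0.97, max_gap = 600, min_probes = 3,
                       mode = c("absolute", "quantile"), genome = NULL) {
  mode <- match.arg(mode)
  stopifnot(max_gap > 0, min_probes >= 1)
  empty <- GenomicRanges::GRanges(score = numeric(0),
                                  probe_count = integer(0))
  if (length(track$value) == 0) return(empty)
  thr <- if (mode == "quantile") {
    if (threshold <= 0 || threshold >= 1) {
      stop("in quantile mode `threshold` must be in (0,1)")
    }
    stats::quantile(track$value, threshold, names = FALSE)
  } else threshold
  chrom <- factor(track$probes$chrom, unique(track$probes$chrom))
  res <- lapply(split(seq_along(chrom), chrom), function(ix) {
    pos <- track$probes$pos[ix]
    v <- track$value[ix]
    qual <- which(v >= thr)
    if (length(qual) == 0) return(NULL)
    new_run <- c(TRUE,
                 diff(qual) > 1 | diff(pos[qual]) > max_gap)
    run_id <- cumsum(new_run)
    keep <- tabulate(run_id) >= min_probes
    if (!any(keep)) return(NULL)
    first <- tapply(qual, run_id, min)[keep]
    last <- tapply(qual, run_id, max)[keep]
    score <- tapply(v[qual], run_id, max)[keep]
    data.frame(chrom = as.character(chrom[ix][1]),
               start = pos[first], end = pos[last],
               score = as.numeric(score),
               probe_count = as.integer(last - first + 1))
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0) return(empty)
  gr <- GenomicRanges::GRanges(
    res$chrom, IRanges::IRanges(res$start, res$end),
    score = res$score, probe_count = res$probe_count
  )
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Summarise a peak set
#'
#' @param peaks A `GRanges` peak set (optionally with `probe_count`).
#' @return A one-row data.frame: `n_peaks`, `total_bp`, `mean_length`,
#'   `median_length`, `min_length`, `max_length`, `mean_probe_count`.
#' @export
peak_summary <- function(peaks) {
  if (length(peaks) == 0) {
    return(data.frame(n_peaks = 0L, total_bp = 0, mean_length = NA_real_,
                      median_length = NA_real_, min_length = NA_real_,
                      max_length = NA_real_, mean_probe_count = NA_real_))
  }
  w <- IRanges::width(peaks)
  data.frame(
    n_peaks = length(peaks),
    total_bp = sum(as.numeric(w)),
    mean_length = mean(w),
    median_length = stats::median(w),
    min_length = min(w),
    max_length = max(w),
    mean_probe_count = if (is.null(peaks$probe_count)) NA_real_ else
      mean(peaks$probe_count)
  )
}
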