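#' Construct a signal track over a probe map
#'
#' A signal track holds one log2 IP/input value per probe of a tiling-array
#' probe map.
#'
#' @param probes A `probe_map` (data.frame with `chrom`, `pos`).
#' @param value Numeric vector, one finite value per probe.
#' @param label Track label.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(probes, value, label = "") {
  stopifnot(inherits(probes, "probe_map") || is.data.frame(probes))
  if (nrow(probes) != length(value)) {
    stop("`value` must have one element per probe")
  }
  if (any(!is.finite(value))) stop("signal values must be finite")
  ok <- tapply(probes$pos, factor(probes$chrom, unique(probes$chrom)),
               function(p) all(diff(p) > 0))
  if (!all(unlist(ok))) stop("probe positions must be strictly increasing per chromosome")
  structure(list(probes = probes, value = as.numeric(value),
                 label = as.character(label)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track '", x$label, "': ", length(x$value), " probes on ",
      length(unique(x$probes$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

same_probe_map <- function(tracks) {
  ref <- tracks[[1]]$probes
  for (t in tracks[-1]) {
    if (!identical(ref$chrom, t$probes$chrom) ||
        !identical(ref$pos, t$probes$pos)) {
      stop("all tracks must share one probe map")
    }
  }
  invisible(ref)
}

#' Quantile-normalize signal tracks between arrays
#'
#' Forces every track to the same distribution — the per-rank mean of the
#' input order statistics — while preserving the rank order within each
#' track. Ties are resolved by average rank. Delegates to
#' [limma::normalizeQuantiles()], the standard between-array normalization.
#'
#' @param tracks List of `signal_track`s sharing one probe map.
#' @return List of normalized `signal_track`s in the same order.
#' @export
quantile_normalize <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  same_probe_map(tracks)
  if (length(tracks) == 1) return(tracks)
  m <- vapply(tracks, function(t) t$value, numeric(length(tracks[[1]]$value)))
  mn <- limma::normalizeQuantiles(m, ties = TRUE)
  lapply(seq_along(tracks), function(i) {
    signal_track(tracks[[i]]$probes, mn[, i], tracks[[i]]$label)
  })
}

#' Median-centre a signal track
#'
#' Shifts all values by a constant so the track median is 0. This is the
#' within-array location adjustment applied to each log-ratio track before
#' between-array normalization.
#'
#' @param track A `signal_track`.
#' @return A `signal_track` with median 0.
#' @export
median_center <- function(track) {
  stopifnot(length(track$value) >= 1)
  signal_track(track$probes, track$value - stats::median(track$value),
               track$label)
}

#' Pool replicate tracks by the per-probe median
#'
#' @param tracks List of replicate `signal_track`s on one probe map.
#' @param label Label for the pooled track.
#' @return A single `signal_track`; for an even number of replicates the
#'   median is the mean of the two central values.
#' @export
pool_replicates <- function(tracks, label = "pooled") {
  stopifnot(length(tracks) >= 1)
  probes <- same_probe_map(tracks)
  if (length(tracks) == 1) {
    return(signal_track(probes, tracks[[1]]$value, label))
  }
  m <- vapply(tracks, function(t) t$value, numeric(length(tracks[[1]]$value)))
  signal_track(probes, apply(m, 1, stats::median), label)
}

#' Smooth a track with a running median along each chromosome
#'
#' The window is centred on each probe and never crosses a chromosome
#' boundary; at chromosome edges it shrinks to the probes available. The
#' median of an even number of values is the mean of the central pair.
#'
#' @param track A `signal_track`.
#' @param window Odd window size in probes (1 = identity; 3 and 5 are the
#'   usual choices for ~300 bp tiling arrays).
#' @return The smoothed `signal_track`.
#' @export
smooth_running_median <- function(track, window = 3) {
  if (window %% 2 == 0 || window < 1) stop("`window` must be a positive odd integer")
  if (window == 1) return(track)
  h <- window %/% 2
  v <- track$value
  chrom <- factor(track$probes$chrom, unique(track$probes$chrom))
  out <- unlist(lapply(split(v, chrom), function(x) {
    n <- length(x)
    if (n <= window) {
      return(vapply(seq_len(n), function(i) {
        stats::median(x[max(1, i - h):min(n, i + h)])
      }, numeric(1)))
    }
    # C-level running median for the interior; windows shrink at the ends
    y <- stats::runmed(x, window, endrule = "keep")
    for (i in c(seq_len(h), (n - h + 1):n)) {
      y[i] <- stats::median(x[max(1, i - h):min(n, i + h)])
    }
    y
  }), use.names = FALSE)
  signal_track(track$probes, out, track$label)
}

#' Subtract a mock-control track
#'
#' Direct per-probe subtraction of a (replicate-pooled) mock
#' immunoprecipitation track, removing nonspecific enrichment shared between
#' the ChIP and the mock.
#'
#' @param track The ChIP `signal_track`.
#' @param mock The mock `signal_track` on the same probe map.
#' @return The difference `signal_track`.
#' @export
subtract_mock <- function(track, mock) {
  same_probe_map(list(track, mock))
  signal_track(track$probes, track$value - mock$value, track$label)
}

#' Run the full probe-level ChIP-chip processing chain
#'
#' Per-track median centring, quantile normalization between arrays (within
#' the ChIP replicate group and within the mock group — the two experiments
#' have genuinely different signal distributions), median pooling of the
#' ChIP replicates, running-median smoothing, and mock subtraction. By
#' default the mock is subtracted after both tracks are smoothed;
#' `subtract_first = TRUE` flips the order.
#'
#' @param chip List of replicate ChIP `signal_track`s.
#' @param mock A mock `signal_track` (or list of mock replicates, pooled by
#'   median).
#' @param window Running-median window (odd; 3 by default, 5 for noisier
#'   factors).
#' @param subtract_first Subtract the mock before smoothing instead of after.
#' @param center Apply per-track median centring (default TRUE).
#' @return The processed `signal_track` ready for peak calling.
#' @export
process_chip_tracks <- function(chip, mock = NULL, window = 3,
                                subtract_first = FALSE, center = TRUE) {
  stopifnot(is.list(chip), length(chip) >= 1)
  if (!is.null(mock) && inherits(mock, "signal_track")) mock <- list(mock)
  if (center) {
    chip <- lapply(chip, median_center)
    mock <- if (is.null(mock)) NULL else lapply(mock, median_center)
  }
  pooled <- pool_replicates(quantile_normalize(chip), label = "chip")
  if (is.null(mock)) {
    return(smooth_running_median(pooled, window))
  }
  mock_pooled <- pool_replicates(quantile_normalize(mock), label = "mock")
  if (subtract_first) {
    smooth_running_median(subtract_mock(pooled, mock_pooled), window)
  } else {
    subtract_mock(smooth_running_median(pooled, window),
                  smooth_running_median(mock_pooled, window))
  }
}

#' Read a signal track from a bedGraph file
#'
#' Each bedGraph record is taken as one probe; the probe centre is the
#' midpoint of the record interval.
#'
#' @param path Path to a 4-column bedGraph-style TSV.
#' @param label Track label (defaults to the file name).
#' @return A `signal_track`.
#' @export
read_bedgraph <- function(path, label = basename(path)) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  pm <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = as.integer(floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2))
  )
  class(pm) <- c("probe_map", "data.frame")
  signal_track(pm, gr$score, label)
}

#' Write a signal track as bedGraph
#'
#' Probes are written as 1 bp records at their centres.
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    track$probes$chrom,
    IRanges::IRanges(track$probes$pos, width = 1),
    score = track$value
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
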