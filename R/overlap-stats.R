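#' Hypergeometric significance of a gene-set overlap
#'
#' The probability of drawing at least the observed overlap when `|b|` genes
#' are drawn without replacement from a universe containing `|a|` "success"
#' genes: `p = P(X >= |a . b|)` for `X ~ Hypergeometric(|U|, |a|, |b|)`.
#' Symmetric in `a` and `b`.
#'
#' @param set_a,set_b Character vectors of gene ids; must be subsets of
#'   `universe`.
#' @param universe Character vector of all testable gene ids.
#' @return A list with `overlap`, `p`, and the sizes `n_a`, `n_b`,
#'   `n_universe`.
#' @export
gene_overlap_hypergeom <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("both gene sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a), length(universe) - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(overlap = k, p = p, n_a = length(set_a), n_b = length(set_b),
       n_universe = length(universe))
}

#' Enrichment of bound genes among differentially expressed genes
#'
#' Joins the expression arm to the binding arm of the pipeline: tests whether
#' the differentially expressed genes are enriched for genes near binding
#' peaks, by the hypergeometric overlap test.
#'
#' @param de_genes Character vector of selected DE gene ids.
#' @param bound_genes Character vector of peak-associated gene ids.
#' @param universe All tested gene ids.
#' @return As [gene_overlap_hypergeom()].
#' @export
de_bound_enrichment <- function(de_genes, bound_genes, universe) {
  gene_overlap_hypergeom(de_genes, bound_genes, universe)
}

# --- plain-vector interval primitives for the bootstrap inner loop --------
# closed integer intervals; merging also joins bookended intervals, which
# leaves total covered length unchanged

.merge_iv <- function(start, end) {
  if (length(start) == 0) return(list(start = integer(0), end = integer(0)))
  o <- order(start)
  s <- start[o]; e <- end[o]
  cme <- cummax(e)
  grp <- cumsum(c(TRUE, s[-1] > cme[-length(cme)] + 1))
  last <- cumsum(tabulate(grp))
  list(start = s[c(1L, last[-length(last)] + 1L)], end = cme[last])
}

# covered-length of the union of two already-merged interval lists
.union_bp <- function(a, b) {
  m <- .merge_iv(c(a$start, b$start), c(a$end, b$end))
  sum(as.numeric(m$end - m$start + 1))
}

# overlap bp between two merged interval lists via inclusion-exclusion
.overlap_bp <- function(a, b) {
  if (length(a$start) == 0 || length(b$start) == 0) return(0)
  wa <- sum(as.numeric(a$end - a$start + 1))
  wb <- sum(as.numeric(b$end - b$start + 1))
  wa + wb - .union_bp(a, b)
}

# split a GRanges into per-chromosome merged plain interval lists
.per_chrom_iv <- function(x, chroms) {
  sn <- as.character(GenomicRanges::seqnames(x))
  out <- lapply(chroms, function(chr) {
    i <- sn == chr
    .merge_iv(GenomicRanges::start(x)[i], GenomicRanges::end(x)[i])
  })
  names(out) <- chroms
  out
}

#' Block-bootstrap significance of basepair overlap between two peak sets
#'
#' The observed statistic is [basepair_overlap()] of `a` and `b`. The null
#' distribution is built by rebuilding `b` chromosome by chromosome: the
#' chromosome is tiled with destination slots of `block_length` bp, and each
#' slot is filled from a source block of the same length whose start is drawn
#' uniformly (with replacement) from the same chromosome; intervals of `b`
#' falling in the source block are transplanted into the slot and clipped at
#' its edges. This preserves the local spatial structure of `b` (interval
#' lengths and short-range clustering within a block) while destroying its
#' long-range alignment with `a`, which stays fixed. Reported are the
#' Z-score, the one-sided empirical p-value with the `+1` floor correction
#' (`p >= 1/(n_iterations+1)`), and a normal-approximation p-value.
#'
#' @param a,b `GRanges` peak sets on `genome`; `b` is the set resampled.
#' @param genome `Seqinfo` with chromosome lengths.
#' @param n_iterations Bootstrap iterations; default 10000.
#' @param block_length Block size in bp; default 100000 (much longer than a
#'   peak, much shorter than a chromosome). Must not exceed the shortest
#'   chromosome.
#' @param seed Integer seed.
#' @return A list of class `overlap_result`: `observed`, `null_mean`,
#'   `null_sd`, `z_score`, `p_empirical`, `p_normal`, `degenerate`,
#'   `n_iterations`, `block_length`.
#' @export
block_bootstrap_overlap <- function(a, b, genome, n_iterations = 10000,
                                    block_length = 100000, seed = 1) {
  stopifnot(n_iterations >= 2, block_length > 0)
  lens <- GenomeInfoDb::seqlengths(genome)
  if (any(is.na(lens))) stop("genome must have defined chromosome lengths")
  if (block_length > min(lens)) {
    stop("block_length must not exceed the shortest chromosome")
  }
  set.seed(seed)
  chroms <- names(lens)
  a_iv <- .per_chrom_iv(a, chroms)
  b_iv <- .per_chrom_iv(b, chroms)
  observed <- basepair_overlap(a, b)
  null <- numeric(n_iterations)
  # per-chromosome constants hoisted out of the bootstrap loop
  slot_starts <- lapply(chroms, function(chr) {
    as.integer(seq(1L, lens[[chr]], by = block_length))
  })
  names(slot_starts) <- chroms
  for (it in seq_len(n_iterations)) {
    tot <- 0
    for (chr in chroms) {
      bb <- b_iv[[chr]]
      nb <- length(bb$start)
      if (nb == 0 || length(a_iv[[chr]]$start) == 0) next
      d <- slot_starts[[chr]]
      L <- lens[[chr]]
      s <- as.integer(floor(stats::runif(length(d)) *
                              (L - block_length + 1))) + 1L
      # all (interval, slot) pairs where the b-interval hits the source block
      hit <- outer(bb$start, s + (block_length - 1L), "<=") &
        outer(bb$end, s, ">=")
      idx <- which(hit, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      qh <- idx[, 1]; sh <- idx[, 2]
      shift <- d[sh] - s[sh]
      ns <- pmax(bb$start[qh] + shift, d[sh])
      slot_end <- pmin(d[sh] + block_length - 1L, L)
      ne <- pmin(bb$end[qh] + shift, slot_end)
      ok <- ne >= ns
      if (!any(ok)) next
      bnew <- .merge_iv(ns[ok], ne[ok])
      tot <- tot + .overlap_bp(a_iv[[chr]], bnew)
    }
    null[it] <- tot
  }
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  degenerate <- null_sd == 0
  z <- if (degenerate) 0 else (observed - null_mean) / null_sd
  p_emp <- (1 + sum(null >= observed)) / (n_iterations + 1)
  p_norm <- if (degenerate) NA_real_ else stats::pnorm(z, lower.tail = FALSE)
  structure(
    list(observed = observed, null_mean = null_mean, null_sd = null_sd,
         z_score = z, p_empirical = p_emp, p_normal = p_norm,
         degenerate = degenerate, n_iterations = n_iterations,
         block_length = block_length),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("block-bootstrap basepair overlap\n")
  cat(sprintf("  observed: %.0f bp; null %.1f +/- %.1f (%d iterations, block %d bp)\n",
              x$observed, x$null_mean, x$null_sd, x$n_iterations,
              x$block_length))
  cat(sprintf("  Z = %.2f, empirical p = %.3g%s\n", x$z_score, x$p_empirical,
              if (x$degenerate) " [degenerate null]" else ""))
  invisible(x)
}
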