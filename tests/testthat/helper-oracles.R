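# Independent brute-force oracles used to freeze expected values.
# Each one deliberately takes a different algorithmic route from the
# implementation it checks.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# per-basepair boolean-mask overlap on small genomes
mask_of <- function(gr, genome) {
  lens <- GenomeInfoDb::seqlengths(genome)
  mask <- logical(sum(lens))
  offset <- c(0, cumsum(lens))[seq_along(lens)]
  names(offset) <- names(lens)
  for (i in seq_along(gr)) {
    chr <- as.character(seqnames(gr)[i])
    mask[(offset[chr] + start(gr)[i]):(offset[chr] + end(gr)[i])] <- TRUE
  }
  mask
}

mask_overlap_bp <- function(a, b, genome) {
  sum(mask_of(a, genome) & mask_of(b, genome))
}

# peak caller reference: scan every probe pair (i, j) and keep maximal
# qualifying runs, the O(n^2) enumeration route
brute_call_peaks <- function(pos, val, chrom, threshold, max_gap, min_probes) {
  out <- NULL
  for (chr in unique(chrom)) {
    p <- pos[chrom == chr]; v <- val[chrom == chr]
    n <- length(p)
    run_ok <- function(i, j) {
      all(v[i:j] >= threshold) &&
        (i == j || all(diff(p[i:j]) <= max_gap))
    }
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (!run_ok(i, j)) next
        maximal <- (i == 1 || !run_ok(i - 1, j)) &&
          (j == n || !run_ok(i, j + 1))
        if (maximal && (j - i + 1) >= min_probes) {
          out <- rbind(out, data.frame(
            chrom = chr, start = p[i], end = p[j],
            score = max(v[i:j]), probe_count = j - i + 1))
        }
      }
    }
  }
  out
}

# literal step-up definition of the BH cutoff
brute_bh <- function(pvals, q) {
  m <- length(pvals)
  ps <- sort(pvals)
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i / m * q) k <- i
  list(p_cutoff = if (k == 0) 0 else ps[k], n_selected = k)
}

# hypergeometric upper tail from the exact pmf via choose()
hyper_tail_choose <- function(N, K, n, k) {
  if (k <= 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# hypergeometric upper tail by enumerating every possible draw (tiny N only)
hyper_tail_combn <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Boolean network reference evaluator: precompute each rule as an explicit
# truth table over its inputs, then update by table lookup
brute_step <- function(net, state, clamps = net$clamps) {
  nxt <- state
  for (node in names(net$rules)) {
    ins <- net$rules[[node]]$inputs
    if (length(ins) == 0) {
      env <- list2env(list(NAND = function(...) !all(...)), parent = baseenv())
      nxt[node] <- as.numeric(eval(net$rules[[node]]$expr, env))
      next
    }
    combos <- as.matrix(expand.grid(rep(list(c(0, 1)), length(ins))))
    colnames(combos) <- ins
    table <- apply(combos, 1, function(row) {
      env <- list2env(as.list(row == 1), parent = baseenv())
      env$NAND <- function(...) !all(...)
      as.numeric(eval(net$rules[[node]]$expr, env))
    })
    key <- sum(state[ins] * 2^(seq_along(ins) - 1)) + 1
    nxt[node] <- table[key]
  }
  if (length(clamps)) nxt[names(clamps)] <- clamps
  nxt
}

make_probe_track <- function(pos, values, chrom = "chr1") {
  pm <- data.frame(chrom = rep(chrom, length.out = length(pos)), pos = pos)
  class(pm) <- c("probe_map", "data.frame")
  signal_track(pm, values)
}

random_granges <- function(n, genome, max_len = 500, disjoint = TRUE) {
  lens <- GenomeInfoDb::seqlengths(genome)
  chr <- sample(names(lens), n, replace = TRUE)
  w <- sample.int(max_len, n, replace = TRUE)
  st <- vapply(seq_len(n), function(i) sample.int(lens[chr[i]] - w[i], 1),
               integer(1))
  gr <- GRanges(chr, IRanges(st, width = w), seqinfo = genome)
  if (disjoint) gr <- reduce(gr)
  sort(gr)
}
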