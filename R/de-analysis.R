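#' Presence filter for an expression matrix
#'
#' Keeps genes whose intensity reaches `intensity_floor` in at least
#' `min_samples` samples, a simple stand-in for array present/absent calls
#' (e.g. "present on at least four arrays").
#'
#' @param expr Genes x samples numeric matrix of log2 intensities.
#' @param min_samples Minimum number of samples at or above the floor.
#' @param intensity_floor Intensity threshold; default the matrix-wide 25th
#'   percentile.
#' @return The filtered matrix (possibly with zero rows).
#' @export
presence_filter <- function(expr, min_samples,
                            intensity_floor = stats::quantile(expr, 0.25)) {
  stopifnot(min_samples <= ncol(expr))
  keep <- rowSums(expr >= intensity_floor) >= min_samples
  expr[keep, , drop = FALSE]
}

#' Per-gene differential expression by ordinary least squares
#'
#' Fits, for every gene, `log2 intensity ~ condition + batch` with batch as
#' fixed-effect indicators, by a single QR decomposition of the shared design
#' matrix. The effect is the induced-vs-control coefficient; the p-value is
#' the two-sided t-test on that coefficient with the residual degrees of
#' freedom. Genes with (numerically) zero residual variance and a nonzero
#' effect are flagged `degenerate` and given the machine-minimum positive
#' p-value.
#'
#' @param expr Genes x samples matrix (after presence filtering).
#' @param design Data.frame with columns `sample` (matching `colnames(expr)`),
#'   `condition` (two levels; "control" is taken as baseline when present),
#'   and optionally `batch`.
#' @return A data.frame of class `de_result`: `gene_id`, `effect` (log2 fold
#'   change), `se`, `t`, `p`, `degenerate`.
#' @export
fit_de <- function(expr, design) {
  stopifnot(all(c("sample", "condition") %in% names(design)))
  design <- design[match(colnames(expr), design$sample), ]
  if (anyNA(design$sample)) stop("design must cover every sample in `expr`")
  cond <- factor(design$condition)
  if (nlevels(cond) != 2) stop("`condition` must have exactly two levels")
  if ("control" %in% levels(cond)) cond <- stats::relevel(cond, "control")
  if (!is.null(design$batch) && length(unique(design$batch)) > 1) {
    X <- stats::model.matrix(~ cond + factor(design$batch))
  } else {
    X <- stats::model.matrix(~ cond)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  y <- t(expr)                       # samples x genes
  fit <- stats::lm.fit(X, y)
  df <- nrow(X) - ncol(X)
  if (df < 1) stop("no residual degrees of freedom")
  coef_i <- 2L                       # the condition coefficient
  res <- as.matrix(fit$residuals)
  sigma2 <- colSums(res^2) / df
  xtxi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * xtxi[coef_i, coef_i])
  effect <- as.matrix(fit$coefficients)[coef_i, ]
  degenerate <- sigma2 <= .Machine$double.eps & abs(effect) > 0
  tstat <- ifelse(se > 0, effect / se, Inf * sign(effect))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[degenerate] <- .Machine$double.xmin
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(gene_id = rownames(expr), effect = unname(effect),
                    se = unname(se), t = unname(tstat), p = unname(p),
                    degenerate = unname(degenerate),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg p-value cutoff at a target FDR
#'
#' The step-up procedure: with sorted p-values `p_(1) <= ... <= p_(m)`, find
#' the largest `k` with `p_(k) <= (k/m) q`; everything at or below `p_(k)` is
#' selected. This converts an FDR level into a concrete p-value cutoff (the
#' style in which array studies report "p cut-off of 0.00285 corresponding to
#' FDR of 5%").
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param q Target FDR level in (0, 1).
#' @return A list with `p_cutoff` (0 when nothing qualifies) and
#'   `n_selected`.
#' @export
bh_cutoff <- function(pvals, q) {
  stopifnot(q > 0, q < 1, all(pvals > 0), all(pvals <= 1))
  m <- length(pvals)
  if (m == 0) return(list(p_cutoff = 0, n_selected = 0L))
  ps <- sort(pvals)
  ok <- which(ps <= seq_len(m) / m * q)
  if (length(ok) == 0) return(list(p_cutoff = 0, n_selected = 0L))
  k <- max(ok)
  list(p_cutoff = ps[k], n_selected = k)
}

#' Select differentially expressed genes at a target FDR
#'
#' Applies [bh_cutoff()] to the p-values of a [fit_de()] result and flags the
#' selected genes.
#'
#' @param de A `de_result` data.frame.
#' @param q Target FDR; default 0.05.
#' @return The `de_result` with added columns `selected` and
#'   `q_cutoff_applied`, plus attributes `p_cutoff` and `n_selected`.
#' @export
select_de <- function(de, q = 0.05) {
  cut <- bh_cutoff(de$p, q)
  de$selected <- de$p <= cut$p_cutoff & cut$n_selected > 0
  de$q_cutoff_applied <- q
  attr(de, "p_cutoff") <- cut$p_cutoff
  attr(de, "n_selected") <- cut$n_selected
  de
}
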