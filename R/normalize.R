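#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over reference genes,
#' of the ratio between a sample's count and the gene's geometric mean
#' across samples. Reference genes are those with strictly positive counts
#' in every sample. Dividing each sample's counts by its factor puts all
#' samples on a common scale.
#'
#' @param counts a [count_matrix()].
#' @return Positive numeric vector of per-sample factors (named).
#' @export
size_factors <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$values
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("no gene has positive counts in every sample; ",
         "use normalize_counts(method = \"cpm\") as a pseudo-reference fallback")
  lg <- log(m[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  factors <- apply(exp(lg - geo), 2, median)
  factors
}

#' Normalize a count matrix
#'
#' `method = "median_ratio"` divides counts by [size_factors()];
#' `method = "cpm"` rescales each sample to a common library size of 1e6
#' (counts per million), available as a fallback when no gene is expressed
#' in all samples.
#'
#' @param counts a [count_matrix()].
#' @param method `"median_ratio"` (default) or `"cpm"`.
#' @return An [expr_matrix()] of normalized non-negative values.
#' @export
normalize_counts <- function(counts, method = c("median_ratio", "cpm")) {
  method <- match.arg(method)
  m <- counts$values
  f <- switch(method,
              median_ratio = size_factors(counts),
              cpm = colSums(m) / 1e6)
  if (any(f <= 0)) stop("non-positive size factor")
  expr_matrix(sweep(m, 2, f, `/`), counts$is_mito)
}

#' Select high-variance genes for subtype discovery
#'
#' Keeps genes whose median normalized value exceeds `median_min` and that
#' are not mitochondrial, ranks them by variance (descending) and returns
#' the top `n_top`. Variance is computed on the normalized scale by
#' default, or on log2(x + 1) with `log_scale = TRUE`. Ties in variance are
#' broken by gene id (lexicographic) for determinism.
#'
#' @param expr an [expr_matrix()] of normalized values.
#' @param n_top number of genes to keep (all survivors if fewer).
#' @param median_min per-gene median threshold (strictly greater-than).
#' @param log_scale rank variance on log2(x + 1) instead of the linear scale.
#' @return An [expr_matrix()] restricted to the selected genes, ordered by
#'   decreasing variance.
#' @export
select_genes <- function(expr, n_top = 5000, median_min = 1, log_scale = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  m <- expr$values
  med <- apply(m, 1, median)
  keep <- med > median_min & !expr$is_mito
  if (!any(keep)) stop("no gene passes the median and mitochondrial filters")
  m <- m[keep, , drop = FALSE]
  v <- if (log_scale) apply(log2(m + 1), 1, var) else apply(m, 1, var)
  ord <- order(-v, rownames(m))
  sel <- ord[seq_len(min(n_top, length(ord)))]
  expr_matrix(m[sel, , drop = FALSE], expr$is_mito[rownames(m)[sel]])
}
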