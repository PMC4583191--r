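#' Smoothed density of gene-gene correlations
#'
#' Gaussian-kernel density of the off-diagonal correlations, the standard
#' visual check of a cleaning step: for a large random gene set the density
#' should be roughly normal and centered at 0, while positive-control genes
#' (known co-regulated sets) should sit clearly in the positive domain.
#' Bandwidth follows Silverman's rule (`bw.nrd0`). With fewer than 10 pairs
#' a histogram-style table is returned instead of a kernel estimate.
#'
#' @param corrs a [correlation_set()].
#' @param grid optional evaluation points; defaults to 512 points spanning
#'   the data plus three bandwidths.
#' @return a list with `table` (data frame `x`, `density`), `mean`,
#'   `median`, `mode` (grid point of maximum density), `bandwidth`, and
#'   `kind` (`"density"` or `"histogram"`).
#' @export
correlation_density <- function(corrs, grid = NULL) {
  stopifnot(inherits(corrs, "correlation_set"))
  v <- offdiag(corrs$corr)
  if (length(v) < 10) {
    h <- graphics::hist(v, breaks = "Sturges", plot = FALSE)
    return(list(table = data.frame(x = h$mids, density = h$density),
                mean = mean(v), median = stats::median(v),
                mode = h$mids[which.max(h$density)],
                bandwidth = NA_real_, kind = "histogram"))
  }
  bw <- stats::bw.nrd0(v)
  if (is.null(grid)) {
    d <- stats::density(v, bw = bw, n = 512)
  } else {
    d <- stats::density(v, bw = bw, n = length(grid),
                        from = min(grid), to = max(grid))
    # exact evaluation on the user grid (density() uses an FFT grid)
    yy <- vapply(grid, function(g) mean(stats::dnorm(g, mean = v, sd = bw)),
                 numeric(1))
    d <- list(x = grid, y = yy)
  }
  list(table = data.frame(x = d$x, density = d$y),
       mean = mean(v), median = stats::median(v),
       mode = d$x[which.max(d$y)], bandwidth = bw, kind = "density")
}

#' Histogram of correlation-test p-values
#'
#' Bins p-values into 100 equal, left-closed right-open bins on `[0, 1]`
#' (the last bin is closed at 1) and reports the count of the first bin
#' `[0, 0.01)` separately, since an excess there signals residual
#' systematic noise inflating correlation significance.
#'
#' @param pvals numeric vector or matrix of p-values in `[0, 1]`; `NA`s
#'   (e.g. a p-value matrix diagonal) are dropped.
#' @return a list with `counts` (length 100), `breaks`, `first_bin_count`,
#'   and `n`.
#' @export
pvalue_histogram <- function(pvals) {
  p <- as.vector(pvals)
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p-values supplied")
  if (min(p) < 0 || max(p) > 1)
    stop("p-values outside [0, 1]")
  idx <- pmin(floor(p * 100) + 1L, 100L)
  counts <- tabulate(idx, nbins = 100L)
  list(counts = counts, breaks = seq(0, 1, by = 0.01),
       first_bin_count = counts[1], n = length(p))
}

#' Modified relative log expression summary
#'
#' Subtracts each gene's median across samples and reports, per sample, the
#' median and interquartile range of the resulting deviations — the
#' summary-only variant of an RLE plot, suited to datasets with too many
#' samples for per-sample boxplots. Well-normalized data has sample medians
#' near 0 and comparable IQRs.
#'
#' @param Y samples-by-genes expression matrix.
#' @return data frame with `sample_id`, `median`, `iqr`.
#' @export
rle_summary <- function(Y) {
  Y <- as_expression_matrix(Y)
  dev <- sweep(Y, 2L, apply(Y, 2L, stats::median), "-")
  data.frame(sample_id = rownames(Y),
             median = apply(dev, 1L, stats::median),
             iqr = apply(dev, 1L, stats::IQR),
             row.names = NULL)
}

#' Principal component projection of samples
#'
#' Scores of the samples on the top principal axes of the gene-centered
#' matrix, with variance-explained fractions, optionally joined with a
#' sample annotation table for coloring by known sources of unwanted
#' variation. Samples separating by a known nuisance factor (batch, site,
#' platform) indicate systematic noise that cleaning should remove.
#'
#' @param Y samples-by-genes expression matrix.
#' @param annotation optional data frame with a `sample_id` column matching
#'   the matrix rows.
#' @param d number of components (default 2), at most `min(m, n)`.
#' @return a list with `scores` (m x d), `var_explained` (length d),
#'   `var_explained_all`, and `annotation` (reordered to the samples, or
#'   `NULL`).
#' @export
pca_projection <- function(Y, annotation = NULL, d = 2) {
  Y <- as_expression_matrix(Y)
  if (d < 1 || d > min(dim(Y)))
    stop("d must be between 1 and min(m, n)")
  Ys <- sweep(Y, 2L, colMeans(Y), "-")
  sv <- svd(Ys, nu = d, nv = 0)
  scores <- sweep(sv$u, 2L, sv$d[seq_len(d)], "*")
  dimnames(scores) <- list(rownames(Y), paste0("PC", seq_len(d)))
  ve_all <- sv$d^2 / sum(sv$d^2)
  ann <- NULL
  if (!is.null(annotation)) {
    if (!"sample_id" %in% names(annotation))
      stop("annotation must contain a sample_id column")
    idx <- match(rownames(Y), annotation$sample_id)
    if (anyNA(idx))
      stop("annotation is missing samples: ",
           paste(utils::head(rownames(Y)[is.na(idx)], 5), collapse = ", "))
    ann <- annotation[idx, , drop = FALSE]
  }
  list(scores = scores, var_explained = ve_all[seq_len(d)],
       var_explained_all = ve_all, annotation = ann)
}
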