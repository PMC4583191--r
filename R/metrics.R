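#' Construct a correlation set
#'
#' A symmetric correlation matrix over a named gene subset together with its
#' provenance: which cleaned version of the data produced it and how many
#' samples were used.
#'
#' @param corr symmetric numeric matrix with unit diagonal and entries in
#'   `[-1, 1]`, dimnames giving the gene identifiers.
#' @param source_label provenance label, e.g. `"raw"`, `"BC"`, `"BC+QN"`,
#'   `"RUV-random"`, `"truth"`.
#' @param m_samples number of samples the estimates are based on.
#' @return an object of class `"correlation_set"`.
#' @export
correlation_set <- function(corr, source_label = "unknown", m_samples = NA_integer_) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("corr must be a square matrix")
  if (is.null(rownames(corr)))
    dimnames(corr) <- list(paste0("gene_", seq_len(nrow(corr))),
                           paste0("gene_", seq_len(nrow(corr))))
  if (max(abs(corr - t(corr))) > 1e-12)
    stop("corr must be symmetric (within 1e-12)")
  if (max(abs(diag(corr) - 1)) > 1e-12)
    stop("corr must have unit diagonal")
  if (min(corr) < -1 - 1e-12 || max(corr) > 1 + 1e-12)
    stop("correlations must lie in [-1, 1]")
  structure(list(corr = corr, gene_ids = rownames(corr),
                 source_label = source_label, m_samples = m_samples),
            class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  v <- offdiag(x$corr)
  cat(sprintf("Correlation set: %d genes (%d pairs), source: %s, m = %s\n",
              length(x$gene_ids), length(v), x$source_label, x$m_samples))
  cat(sprintf("  off-diagonal r: mean %.3f, median %.3f, mean |r| %.3f\n",
              mean(v), stats::median(v), mean(abs(v))))
  invisible(x)
}

# upper-triangle off-diagonal values, column-major order
offdiag <- function(M) M[upper.tri(M)]

#' Pearson correlation matrix of an expression matrix
#'
#' Standard Pearson correlation over samples for each pair of (selected)
#' genes. Genes with zero variance are excluded with a warning and reported
#' in the `"excluded"` attribute; the estimate is invariant to per-gene
#' affine rescaling of the input.
#'
#' @param Y samples-by-genes expression matrix with at least 3 samples.
#' @param genes optional gene identifiers to restrict to (default: all).
#' @param source_label provenance label stored in the result.
#' @return a [correlation_set()].
#' @export
pearson_matrix <- function(Y, genes = NULL, source_label = "raw") {
  Y <- as_expression_matrix(Y)
  if (nrow(Y) < 3)
    stop("Pearson correlation needs at least 3 samples")
  if (!is.null(genes))
    Y <- Y[, resolve_genes(Y, genes), drop = FALSE]
  sds <- apply(Y, 2L, stats::sd)
  excluded <- colnames(Y)[sds == 0]
  if (length(excluded) > 0) {
    warning("excluding ", length(excluded), " zero-variance gene(s): ",
            paste(utils::head(excluded, 5), collapse = ", "))
    Y <- Y[, sds > 0, drop = FALSE]
  }
  if (ncol(Y) < 2) stop("fewer than 2 genes with nonzero variance")
  R <- stats::cor(Y)
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- 1
  R <- (R + t(R)) / 2
  out <- correlation_set(R, source_label = source_label, m_samples = nrow(Y))
  attr(out, "excluded") <- excluded
  out
}

# clip correlations away from +/-1 before arctanh; counts clipped entries
clip_corr <- function(r, bound = 1 - 1e-6) {
  n_clip <- sum(abs(r) > bound)
  r[r > bound] <- bound
  r[r < -bound] <- -bound
  attr(r, "clipping_count") <- n_clip
  r
}

check_same_genes <- function(est, truth) {
  stopifnot(inherits(est, "correlation_set"), inherits(truth, "correlation_set"))
  if (length(est$gene_ids) != length(truth$gene_ids) ||
      !setequal(est$gene_ids, truth$gene_ids))
    stop("estimated and true correlation sets cover different gene sets")
}

#' Squared average Fisher-z error of correlation estimates
#'
#' A norm similar to the squared Frobenius norm:
#' `FN^2 = 2 * sum_{i<j} (arctanh(r_hat_ij) - arctanh(r_ij))^2 / (n (n-1))`,
#' the squared average error of the Fisher z-transformed correlation
#' estimates over all off-diagonal gene pairs; 0 iff the estimates equal the
#' truth everywhere (after clipping). Correlation magnitudes are clipped to
#' `1 - 1e-6` before the arctanh so boundary estimates stay finite.
#'
#' @param est,truth [correlation_set()]s over the same genes.
#' @return a single non-negative number; attribute `"clipping_count"` gives
#'   the number of clipped entries.
#' @export
fn_squared <- function(est, truth) {
  check_same_genes(est, truth)
  E <- est$corr[truth$gene_ids, truth$gene_ids]
  re <- clip_corr(offdiag(E))
  rt <- clip_corr(offdiag(truth$corr))
  out <- mean((atanh(re) - atanh(rt))^2)
  attr(out, "clipping_count") <- attr(re, "clipping_count") +
    attr(rt, "clipping_count")
  out
}

#' Percentage of correlation estimates with the wrong sign
#'
#' `100 * #\{pairs: sign(r_hat) != sign(r)\} / #\{pairs: r != 0\}`, computed
#' over off-diagonal pairs with nonzero true correlation. A zero estimate on
#' a truly correlated pair counts as wrong.
#'
#' @param est,truth [correlation_set()]s over the same genes.
#' @return a percentage in `[0, 100]`.
#' @export
wrong_sign_pct <- function(est, truth) {
  check_same_genes(est, truth)
  E <- est$corr[truth$gene_ids, truth$gene_ids]
  re <- offdiag(E)
  rt <- offdiag(truth$corr)
  eligible <- rt != 0
  if (!any(eligible))
    stop("undefined metric: no gene pairs with nonzero true correlation")
  100 * mean(sign(re[eligible]) != sign(rt[eligible]))
}

#' Per-pair p-values for zero correlation
#'
#' Two-sided p-values from the t-statistic `t = r sqrt((m-2)/(1-r^2))` on
#' `m - 2` degrees of freedom, testing each pair's correlation against zero.
#' Estimates at `|r| = 1` are clipped to `1 - 1e-6` first.
#'
#' @param corrs a [correlation_set()] with `m_samples >= 4`.
#' @return a symmetric matrix of p-values with `NA` on the diagonal.
#' @export
correlation_pvalues <- function(corrs) {
  stopifnot(inherits(corrs, "correlation_set"))
  m <- corrs$m_samples
  if (is.na(m) || m < 4)
    stop("correlation t-test needs m >= 4 samples")
  r <- clip_corr(corrs$corr)
  tt <- r * sqrt((m - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = m - 2)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(corrs$corr)
  p
}

#' ECDF of absolute gene-gene correlations
#'
#' Right-continuous empirical cumulative distribution of the off-diagonal
#' `|r|`, the standard display for comparing positive-control against random
#' gene sets across cleaning methods.
#'
#' @param corrs a [correlation_set()] with at least 2 genes.
#' @return a list with `table` (sorted `|r|` and cumulative fraction) and
#'   `fun`, a function evaluable at arbitrary points.
#' @export
ecdf_abs_correlations <- function(corrs) {
  stopifnot(inherits(corrs, "correlation_set"))
  v <- abs(offdiag(corrs$corr))
  if (length(v) == 0) stop("empty correlation set")
  f <- stats::ecdf(v)
  vs <- sort(v)
  list(table = data.frame(abs_r = vs, cum_frac = f(vs)), fun = f)
}

#' Rank shifts of focus gene pairs between two correlation sets
#'
#' Ranks all off-diagonal pairs of the common gene universe by absolute
#' correlation (highest = rank 1, average ranks on ties) in both sets, and
#' returns `rank_in_reference - rank_in_cleaned` for each focus pair:
#' positive differences mean the pair moved up (became relatively stronger)
#' after cleaning.
#'
#' @param reference,cleaned [correlation_set()]s over the identical gene
#'   universe.
#' @param focus_pairs two-column matrix or data frame of gene identifiers.
#' @return data frame with the pair and its rank in each set and the
#'   difference.
#' @export
rank_differences <- function(reference, cleaned, focus_pairs) {
  check_same_genes(reference, cleaned)
  ids <- reference$gene_ids
  C <- cleaned$corr[ids, ids]
  pair_idx <- which(upper.tri(reference$corr), arr.ind = TRUE)
  rank_ref <- rank(-abs(reference$corr[upper.tri(reference$corr)]))
  rank_cln <- rank(-abs(C[upper.tri(C)]))
  key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = ":")
  lookup <- stats::setNames(seq_len(nrow(pair_idx)),
                            key(pair_idx[, 1], pair_idx[, 2]))
  focus_pairs <- as.matrix(focus_pairs)
  if (ncol(focus_pairs) != 2) stop("focus_pairs must have two columns")
  i <- match(focus_pairs[, 1], ids)
  j <- match(focus_pairs[, 2], ids)
  if (anyNA(i) || anyNA(j))
    stop("focus pair gene absent from the correlation sets")
  if (any(i == j)) stop("focus pairs must be two distinct genes")
  pos <- lookup[key(i, j)]
  data.frame(gene1 = focus_pairs[, 1], gene2 = focus_pairs[, 2],
             rank_reference = rank_ref[pos], rank_cleaned = rank_cln[pos],
             rank_difference = rank_ref[pos] - rank_cln[pos],
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment utility
#'
#' Convenience wrapper around [stats::p.adjust()] for downstream use (e.g.
#' candidate prioritization); the diagnostic p-value histograms in this
#' package deliberately use raw p-values.
#'
#' @param p numeric vector or matrix of p-values.
#' @return adjusted p-values with the same shape.
#' @export
adjust_bh <- function(p) {
  out <- stats::p.adjust(as.vector(p), method = "BH")
  if (is.matrix(p)) out <- matrix(out, nrow(p), ncol(p), dimnames = dimnames(p))
  out
}

#' Accuracy report comparing estimated to true correlations
#'
#' Bundles the two headline accuracy measures — [fn_squared()] and
#' [wrong_sign_pct()] — with bookkeeping: the number of pairs evaluated, the
#' number of pairs eligible for the wrong-sign rate (nonzero true
#' correlation), and how many correlations were clipped at the arctanh
#' boundary.
#'
#' @param est,truth [correlation_set()]s over the same genes.
#' @return a list of class `"metric_report"`.
#' @export
metric_report <- function(est, truth) {
  fn2 <- fn_squared(est, truth)
  rt <- offdiag(truth$corr)
  ws <- if (any(rt != 0)) wrong_sign_pct(est, truth) else NA_real_
  structure(list(fn2 = as.numeric(fn2), ws_pct = ws,
                 n_pairs = length(rt), n_pairs_nonzero = sum(rt != 0),
                 clipping_count = attr(fn2, "clipping_count"),
                 source_label = est$source_label),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Correlation accuracy [%s]: FN2 = %.4g, %%WS = %s (%d pairs, %d with r != 0)\n",
              x$source_label, x$fn2,
              if (is.na(x$ws_pct)) "n/a" else sprintf("%.2f", x$ws_pct),
              x$n_pairs, x$n_pairs_nonzero))
  invisible(x)
}
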