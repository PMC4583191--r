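#' Quantile normalization
#'
#' Classic quantile normalization across samples: within each sample, the
#' i-th order statistic is replaced by the mean of the i-th order statistics
#' over all samples, so afterwards every sample shares an identical sorted
#' value vector. Ties within a sample receive the mean of the values they
#' would have been assigned. Delegates to [limma::normalizeQuantiles()]
#' (with `ties = TRUE`) on the transposed matrix, since limma normalizes
#' columns-as-arrays.
#'
#' @param Y samples-by-genes expression matrix with no missing values.
#' @return the quantile-normalized matrix, same shape and identifiers.
#' @export
quantile_normalize <- function(Y) {
  Y <- as_expression_matrix(Y)
  if (nrow(Y) < 2) {
    warning("single sample: quantile normalization is the identity")
    return(Y)
  }
  out <- t(limma::normalizeQuantiles(t(Y), ties = TRUE))
  dimnames(out) <- dimnames(Y)
  out
}

#' Per-sample background-offset removal (BC surrogate)
#'
#' A deliberately minimal, platform-free stand-in for intensity-level
#' background correction: subtracts from each sample its `quantile_floor`
#' quantile, i.e. removes a per-sample additive offset on the log scale.
#' Intensity-model background correction proper (e.g. normexp) needs raw
#' probe data and is out of scope; results derived from this function are
#' labelled `"BC-surrogate"`.
#'
#' @param Y samples-by-genes log-scale expression matrix.
#' @param quantile_floor quantile level of the per-sample offset (default
#'   0.01).
#' @return the shifted matrix; attribute `"offsets"` holds the per-sample
#'   offsets removed.
#' @export
background_correct <- function(Y, quantile_floor = 0.01) {
  Y <- as_expression_matrix(Y)
  offs <- apply(Y, 1L, stats::quantile, probs = quantile_floor, names = FALSE)
  out <- sweep(Y, 1L, offs, "-")
  dimnames(out) <- dimnames(Y)
  attr(out, "offsets") <- stats::setNames(offs, rownames(Y))
  out
}
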