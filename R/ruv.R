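#' Estimate unwanted-variation factors from negative-control genes
#'
#' Performs the factor-analysis step of RUV-random: a singular value
#' decomposition of the centered negative-control submatrix `Y*_c`. The
#' estimated factor matrix is `W = U_k D_k`, the k leading left singular
#' vectors scaled by their singular values, so that the ridge parameter of
#' [estimate_alpha_ridge()] is on the scale of squared singular values. The
#' orthonormal basis `U_k` and the full singular value spectrum are retained
#' for diagnostics (scree plots) and invariant checks.
#'
#' @param Ystar gene-centered expression matrix (see [center_genes()]).
#' @param controls negative-control gene identifiers (character or
#'   [gene_set()]); all must be columns of `Ystar`.
#' @param k assumed dimension of the unwanted variation, `0 <= k <=
#'   min(m, |c|)`. `k = 0` yields an empty factor matrix and downstream
#'   cleaning is the identity.
#' @return an object of class `"ruv_fit"`: list with elements `W` (m x k),
#'   `U` (m x k orthonormal basis), `singular_values` (all min(m, |c|)
#'   values), `k`, `control_ids`, `m`, and placeholders for the ridge step.
#' @export
fit_unwanted_variation <- function(Ystar, controls, k) {
  Ystar <- as_expression_matrix(Ystar)
  if (!is_centered(Ystar))
    stop("Ystar must be gene-centered; call center_genes() first")
  control_ids <- resolve_genes(Ystar, controls)
  m <- nrow(Ystar)
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k != round(k))
    stop("k must be a single non-negative integer")
  if (k > min(m, length(control_ids)))
    stop("k = ", k, " exceeds min(m, number of controls) = ",
         min(m, length(control_ids)))
  Yc <- Ystar[, control_ids, drop = FALSE]
  if (all(Yc == 0))
    stop("degenerate input: control submatrix is exactly zero")
  sv <- svd(Yc, nu = min(m, length(control_ids)), nv = 0)
  if (k > 0) {
    U <- sv$u[, seq_len(k), drop = FALSE]
    W <- sweep(U, 2L, sv$d[seq_len(k)], "*")
  } else {
    U <- matrix(0, m, 0)
    W <- matrix(0, m, 0)
  }
  structure(
    list(W = W, U = U, singular_values = sv$d, k = k,
         control_ids = control_ids, m = m, n = ncol(Ystar),
         gene_ids = colnames(Ystar), sample_ids = rownames(Ystar),
         alpha = NULL, nu = NULL),
    class = "ruv_fit")
}

#' Ridge-estimate the unwanted-variation coefficients
#'
#' The regression step of RUV-random: since the factor of interest is
#' unobserved, `Y*` is ridge-regressed on the estimated factors alone,
#' `alpha = (W'W + nu I_k)^{-1} W' Y*`, over all genes (not just controls).
#' The ridge parameter `nu >= 0` controls how aggressively variation aligned
#' with the estimated factors is removed: `nu = 0` is ordinary least squares;
#' as `nu` grows, `alpha` shrinks to zero and cleaning tends to the identity.
#' If the biological signal is correlated with the unwanted variation the
#' least-squares estimate is biased towards removing signal; a positive `nu`
#' mitigates (but cannot eliminate) this.
#'
#' @param Ystar gene-centered expression matrix used in the fit.
#' @param fit an `"ruv_fit"` from [fit_unwanted_variation()].
#' @param nu non-negative ridge parameter, on the scale of squared singular
#'   values of the control submatrix (see [suggest_nu_grid()]).
#' @return the fit with `alpha` (k x n) and `nu` filled in.
#' @export
estimate_alpha_ridge <- function(Ystar, fit, nu) {
  stopifnot(inherits(fit, "ruv_fit"))
  Ystar <- as_expression_matrix(Ystar)
  if (!is_centered(Ystar))
    stop("Ystar must be gene-centered; call center_genes() first")
  if (!is.numeric(nu) || length(nu) != 1 || nu < 0)
    stop("nu must be a single non-negative real")
  if (nrow(Ystar) != fit$m)
    stop("sample dimension of Ystar does not match the fit")
  k <- fit$k
  if (k == 0) {
    fit$alpha <- matrix(0, 0, ncol(Ystar), dimnames = list(NULL, colnames(Ystar)))
    fit$nu <- nu
    return(fit)
  }
  G <- crossprod(fit$W) + nu * diag(k)
  alpha <- tryCatch(
    solve(G, crossprod(fit$W, Ystar)),
    error = function(e)
      stop("W'W + nu*I is numerically singular (rank-deficient factors with ",
           "nu = 0); choose nu > 0", call. = FALSE))
  dimnames(alpha) <- list(paste0("W", seq_len(k)), colnames(Ystar))
  fit$alpha <- alpha
  fit$nu <- nu
  fit
}

#' Subtract the estimated unwanted variation
#'
#' The removal step of RUV-random: returns `Y* - W alpha`, the noise-removed
#' centered expression data. Since both `Y*` and the columns of `W` are
#' centered, the subtraction can perturb gene means only at floating-point
#' level; the result is re-centered as numerical hygiene.
#'
#' @param Ystar gene-centered expression matrix.
#' @param fit a complete `"ruv_fit"` (after [estimate_alpha_ridge()]).
#' @return the cleaned, gene-centered matrix with the same identifiers.
#' @export
remove_unwanted_variation <- function(Ystar, fit) {
  stopifnot(inherits(fit, "ruv_fit"))
  if (is.null(fit$alpha))
    stop("fit is incomplete: run estimate_alpha_ridge() first")
  Ystar <- as_expression_matrix(Ystar)
  if (!is_centered(Ystar))
    stop("Ystar must be gene-centered; call center_genes() first")
  if (nrow(Ystar) != fit$m || ncol(Ystar) != ncol(fit$alpha))
    stop("dimensions of Ystar do not match the fit")
  cleaned <- Ystar - fit$W %*% fit$alpha
  stopifnot(max(abs(colMeans(cleaned))) < 1e-6 * (1 + max(abs(cleaned))))
  cleaned <- sweep(cleaned, 2L, colMeans(cleaned), "-")
  dimnames(cleaned) <- dimnames(Ystar)
  attr(cleaned, "centered") <- TRUE
  cleaned
}

#' Clean expression data with RUV-random for correlation analysis
#'
#' The four-step RUV-random procedure for gene co-expression estimation,
#' under the model `Y = X beta + W alpha + eps` with unobserved factor of
#' interest `X` and unobserved unwanted variation `W`:
#'
#' 1. center each gene across samples, `Y* = (I - J/m) Y`;
#' 2. estimate `W` by SVD factor analysis on the centered negative-control
#'    genes `Y*_c` (requires a choice of `k`);
#' 3. estimate `alpha` by ridge regression of `Y*` on `W`,
#'    `alpha = (W'W + nu I)^{-1} W' Y*`;
#' 4. subtract `W alpha` from `Y*`.
#'
#' Both `k` (noise dimension) and `nu` (ridge penalty) are analyst choices;
#' judge them with the diagnostics in this package (scree plot of control
#' singular values via [plot.ruv_random()], [correlation_density()] of random
#' and positive-control genes, [rle_summary()], [pca_projection()]).
#'
#' @param Y samples-by-genes log-scale expression matrix (uncentered is
#'   fine).
#' @param controls negative-control gene identifiers; needs at least `k`
#'   controls.
#' @param k non-negative integer, assumed dimension of unwanted variation.
#' @param nu non-negative ridge parameter; default `0.01 * d1^2` with `d1`
#'   the leading control singular value, a light penalty that keeps the
#'   least-squares behaviour while guarding against rank deficiency.
#' @return an object of class `"ruv_random"`; use [residuals()] for the
#'   cleaned matrix, [coef()] for `alpha`, [fitted()] for the removed
#'   component `W alpha`, [plot()] for the scree diagnostic.
#' @examples
#' sim <- simulate_coexpression(simulation_design(m = 60, n = 100,
#'   n_signal = 40, n_blocks = 4, seed = 1))
#' fit <- ruv_random(sim$Y, sim$controls, k = 3)
#' fit
#' cleaned <- residuals(fit)
#' @export
ruv_random <- function(Y, controls, k, nu = NULL) {
  cl <- match.call()
  Ystar <- center_genes(Y)
  fit <- fit_unwanted_variation(Ystar, controls, k)
  if (is.null(nu))
    nu <- if (fit$k > 0) 0.01 * fit$singular_values[1]^2 else 0
  fit <- estimate_alpha_ridge(Ystar, fit, nu)
  cleaned <- remove_unwanted_variation(Ystar, fit)
  tot <- sum(Ystar^2)
  removed <- sum((fit$W %*% fit$alpha)^2)
  out <- fit
  out$cleaned <- cleaned
  out$centered <- Ystar
  out$var_removed <- if (tot > 0) removed / tot else 0
  out$call <- cl
  class(out) <- c("ruv_random", "ruv_fit")
  out
}

#' @export
print.ruv_random <- function(x, ...) {
  cat("RUV-random fit for correlation analysis\n")
  cat(sprintf("  samples: %d, genes: %d, negative controls: %d\n",
              x$m, x$n, length(x$control_ids)))
  cat(sprintf("  k = %d, nu = %.6g\n", x$k, x$nu))
  cat(sprintf("  proportion of centered variance removed: %.3f\n",
              x$var_removed))
  invisible(x)
}

#' @export
summary.ruv_random <- function(object, ...) {
  d <- object$singular_values
  structure(
    list(k = object$k, nu = object$nu, m = object$m, n = object$n,
         n_controls = length(object$control_ids),
         var_removed = object$var_removed,
         singular_values = d,
         scree = d^2 / sum(d^2)),
    class = "summary.ruv_random")
}

#' @export
print.summary.ruv_random <- function(x, ...) {
  cat("RUV-random fit\n")
  cat(sprintf("  m = %d samples, n = %d genes, |c| = %d negative controls\n",
              x$m, x$n, x$n_controls))
  cat(sprintf("  k = %d, nu = %.6g, variance removed = %.3f\n",
              x$k, x$nu, x$var_removed))
  cat("  leading control singular values (share of control variance):\n")
  nd <- min(10, length(x$singular_values))
  for (i in seq_len(nd))
    cat(sprintf("    d%-2d = %8.3f  (%.3f)\n", i, x$singular_values[i],
                x$scree[i]))
  invisible(x)
}

#' @export
coef.ruv_random <- function(object, ...) object$alpha

#' Cleaned expression data from an RUV-random fit
#'
#' The residuals of the ridge regression of `Y*` on the estimated factors,
#' i.e. the noise-removed, centered expression matrix.
#' @param object an `"ruv_random"` fit.
#' @param ... ignored.
#' @export
residuals.ruv_random <- function(object, ...) object$cleaned

#' @export
fitted.ruv_random <- function(object, ...) object$W %*% object$alpha

#' Scree plot of control-gene singular values
#'
#' Plots the singular value spectrum of the centered negative-control
#' submatrix to aid the choice of `k`: a sharp elbow suggests the dimension
#' of the systematic noise.
#' @param x an `"ruv_random"` or `"ruv_fit"` object.
#' @param n_show number of singular values to display.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ruv_random <- function(x, n_show = min(20, length(x$singular_values)), ...) {
  d <- x$singular_values[seq_len(n_show)]
  graphics::plot(seq_along(d), d, type = "b", xlab = "component",
                 ylab = "singular value",
                 main = "Negative-control singular values", ...)
  if (x$k > 0) graphics::abline(v = x$k + 0.5, lty = 2)
  invisible(x)
}

#' Suggested ridge-parameter grid
#'
#' RUV-random leaves `nu` to the analyst. This helper returns a grid spanning
#' no penalty to effectively switching cleaning off, scaled by the squared
#' leading singular value of the control submatrix so the grid is comparable
#' across datasets: `nu` in `{0, 1e-4, 1e-3, ..., 1e2} * d1^2`. Evaluate
#' candidates with [correlation_density()] on random genes (want a tight
#' density centered at 0) and positive controls (want a positively shifted
#' density).
#'
#' @param fit an `"ruv_fit"` or `"ruv_random"` object.
#' @return numeric vector of candidate `nu` values.
#' @export
suggest_nu_grid <- function(fit) {
  stopifnot(inherits(fit, "ruv_fit"))
  d1 <- if (length(fit$singular_values)) fit$singular_values[1] else 1
  c(0, 10^seq(-4, 2)) * d1^2
}
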