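#' Specify a co-expression simulation design
#'
#' Describes a seeded draw from the linear model `Y = X beta + W alpha + eps`
#' with a known gene-gene correlation structure, designated negative-control
#' genes, and a tunable dependence between the biological signal `X` and the
#' unwanted variation `W`.
#'
#' Signal genes are partitioned into blocks; each block has one shared
#' standard-normal factor (a column of `X`). A signal gene `j` in block `b`
#' has overall biological scale `w_j` drawn from `+/- Uniform(loading_range)`
#' (random sign); it loads `sqrt(within_block_corr) * w_j` on its block
#' factor and carries an independent idiosyncratic biological component with
#' standard deviation `sqrt(1 - within_block_corr) * w_j`. The true
#' correlation between two genes of the same block is therefore exactly
#' `+/- within_block_corr` (sign given by the loading signs) and 0 across
#' blocks, so the average within-block correlation magnitude is controlled
#' directly. Non-signal genes carry no biological variation (the
#' housekeeping-gene idealisation) and form the negative-control pool.
#'
#' Unwanted variation is `W = sqrt(c) X A + sqrt(1 - c) G` with `A` a random
#' `p x k_true` mixing matrix with unit-norm columns and `G` standard normal;
#' `c = noise_signal_mix = 0` gives `W` independent of `X` in expectation,
#' and increasing `c` increases the realized average `|Cor(W, X)|`. The
#' loadings `alpha` are `N(0, sigma_alpha^2)` and `eps` is
#' `N(0, sigma_eps^2)` white measurement noise; no measured background noise
#' is simulated.
#'
#' The defaults describe a noise-dominant microarray-like regime: systematic
#' noise strong enough that roughly half of raw-data correlation signs are
#' wrong, while the biological structure (moderate within-block correlation
#' ~0.4) is fully recoverable once the noise factors are removed. See the
#' methods vignette for how the noise scales were fixed.
#'
#' @param m number of samples.
#' @param n number of genes.
#' @param n_signal number of genes carrying biological signal.
#' @param n_blocks number of correlated signal blocks; ignored when
#'   `block_sizes` is given.
#' @param block_sizes integer partition of `n_signal` into blocks.
#' @param loading_range length-2 positive range for the absolute biological
#'   scale of signal genes.
#' @param within_block_corr target absolute true correlation within a block,
#'   in `[0, 1)`.
#' @param k_true dimension of the unwanted variation.
#' @param sigma_alpha standard deviation of the noise loadings `alpha`.
#' @param sigma_eps standard deviation of the white measurement noise.
#' @param noise_signal_mix mixing coefficient `c` in `[0, 1)` between signal
#'   factors and the unwanted-variation factors.
#' @param control_fraction fraction of non-signal genes labelled as negative
#'   controls.
#' @param contamination fraction of signal genes wrongly relabelled as
#'   negative controls (misspecified-control scenarios).
#' @param seed integer seed; every draw is reproducible from it.
#' @return an object of class `"simulation_design"`.
#' @export
simulation_design <- function(m = 180, n = 500, n_signal = 250,
                              n_blocks = 10, block_sizes = NULL,
                              loading_range = c(0.3, 1.0),
                              within_block_corr = 0.4,
                              k_true = 3,
                              sigma_alpha = 1.65,
                              sigma_eps = 0.48,
                              noise_signal_mix = 0,
                              control_fraction = 1,
                              contamination = 0,
                              seed = 1L) {
  if (is.null(block_sizes)) {
    if (n_signal > 0) {
      if (n_signal %% n_blocks != 0)
        stop("n_signal must be divisible by n_blocks, or give block_sizes")
      block_sizes <- rep(n_signal / n_blocks, n_blocks)
    } else block_sizes <- integer(0)
  }
  design <- structure(
    list(m = m, n = n, n_signal = n_signal, block_sizes = as.integer(block_sizes),
         loading_range = loading_range, within_block_corr = within_block_corr,
         k_true = as.integer(k_true), sigma_alpha = sigma_alpha,
         sigma_eps = sigma_eps, noise_signal_mix = noise_signal_mix,
         control_fraction = control_fraction, contamination = contamination,
         seed = as.integer(seed)),
    class = "simulation_design")
  validate_design(design)
  design
}

validate_design <- function(d) {
  if (d$m < 2 || d$n < 2) stop("invalid design: need m >= 2 and n >= 2")
  if (d$n_signal > d$n) stop("invalid design: n_signal exceeds n")
  if (sum(d$block_sizes) != d$n_signal)
    stop("invalid design: block_sizes must partition n_signal")
  if (any(d$block_sizes <= 0)) stop("invalid design: empty block")
  if (length(d$loading_range) != 2 || any(d$loading_range <= 0) ||
      d$loading_range[1] > d$loading_range[2])
    stop("invalid design: loading_range must be a positive increasing pair")
  if (d$within_block_corr < 0 || d$within_block_corr >= 1)
    stop("invalid design: within_block_corr must be in [0, 1)")
  if (d$noise_signal_mix < 0 || d$noise_signal_mix >= 1)
    stop("invalid design: noise_signal_mix must be in [0, 1)")
  if (d$sigma_alpha <= 0 || d$sigma_eps <= 0)
    stop("invalid design: noise scales must be > 0")
  if (d$k_true < 0) stop("invalid design: k_true must be >= 0")
  if (d$control_fraction <= 0 || d$control_fraction > 1)
    stop("invalid design: control_fraction must be in (0, 1]")
  if (d$contamination < 0 || d$contamination > 1)
    stop("invalid design: contamination must be in [0, 1]")
  invisible(d)
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("Co-expression simulation design\n")
  cat(sprintf("  m = %d samples, n = %d genes (%d signal in %d blocks)\n",
              x$m, x$n, x$n_signal, length(x$block_sizes)))
  cat(sprintf("  within-block |r| = %.2f, loadings |w| ~ U(%.2f, %.2f)\n",
              x$within_block_corr, x$loading_range[1], x$loading_range[2]))
  cat(sprintf("  k_true = %d, sigma_alpha = %.3f, sigma_eps = %.3f, mix c = %.2f\n",
              x$k_true, x$sigma_alpha, x$sigma_eps, x$noise_signal_mix))
  cat(sprintf("  controls: %.0f%% of non-signal genes, contamination %.0f%%, seed %d\n",
              100 * x$control_fraction, 100 * x$contamination, x$seed))
  invisible(x)
}

#' Draw a dataset from a simulation design
#'
#' Generates `Y = X beta + B + W alpha + eps` (with `B` the idiosyncratic
#' biological component described in [simulation_design()]), the generating
#' truth, and the designated negative-control set. Reproducible: the same
#' design (including its seed) yields byte-identical output; the caller's RNG
#' stream is left untouched.
#'
#' @param design a [simulation_design()].
#' @return a list of class `"coexpression_sim"` with elements `Y` (m x n
#'   samples-by-genes matrix), `truth` (class `"simulation_truth"`: `X`,
#'   `beta`, `idio_sd`, `W`, `alpha`, `eps`, `true_corr`, `signal_ids`,
#'   `realized_cor_wx`), and `controls` (a [gene_set()]).
#' @export
simulate_coexpression <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  validate_design(design)
  with_seed(design$seed, {
    m <- design$m; n <- design$n
    p <- length(design$block_sizes)
    k <- design$k_true
    gene_ids <- sprintf("gene_%03d", seq_len(n))
    sample_ids <- sprintf("sample_%03d", seq_len(m))
    block <- rep(seq_len(p), design$block_sizes)          # block of signal gene
    signal_idx <- seq_len(design$n_signal)

    X <- matrix(stats::rnorm(m * p), m, p)
    rho <- design$within_block_corr
    w <- numeric(n)
    s <- numeric(n)
    beta <- matrix(0, p, n)
    idio_sd <- numeric(n)
    if (design$n_signal > 0) {
      w[signal_idx] <- stats::runif(design$n_signal, design$loading_range[1],
                                    design$loading_range[2])
      s[signal_idx] <- sample(c(-1, 1), design$n_signal, replace = TRUE)
      beta[cbind(block, signal_idx)] <- s[signal_idx] * w[signal_idx] * sqrt(rho)
      idio_sd[signal_idx] <- w[signal_idx] * sqrt(1 - rho)
    }
    B <- matrix(stats::rnorm(m * n), m, n)
    B <- sweep(B, 2L, idio_sd, "*")

    cc <- design$noise_signal_mix
    if (k > 0) {
      A <- matrix(stats::rnorm(p * k), p, k)
      A <- sweep(A, 2L, sqrt(colSums(A^2)), "/")
      G <- matrix(stats::rnorm(m * k), m, k)
      W <- sqrt(cc) * X %*% A + sqrt(1 - cc) * G
      alpha <- matrix(stats::rnorm(k * n, sd = design$sigma_alpha), k, n)
    } else {
      A <- matrix(0, p, 0)
      W <- matrix(0, m, 0)
      alpha <- matrix(0, 0, n)
    }
    eps <- matrix(stats::rnorm(m * n, sd = design$sigma_eps), m, n)
    Y <- X %*% beta + B + W %*% alpha + eps
    dimnames(Y) <- list(sample_ids, gene_ids)
    dimnames(beta) <- list(if (p > 0) paste0("X", seq_len(p)), gene_ids)

    truth <- structure(
      list(X = X, beta = beta, idio_sd = stats::setNames(idio_sd, gene_ids),
           W = W, alpha = alpha, eps = eps,
           signal_ids = gene_ids[signal_idx],
           true_corr = analytic_true_corr(beta, idio_sd, gene_ids),
           design = design),
      class = "simulation_truth")
    truth$realized_cor_wx <- realized_noise_signal_correlation(truth)

    nonsignal <- setdiff(gene_ids, truth$signal_ids)
    if (length(nonsignal) == 0)
      stop("invalid design: no non-signal genes available as negative controls")
    n_ctrl <- max(1L, round(design$control_fraction * length(nonsignal)))
    control_ids <- if (n_ctrl < length(nonsignal))
      sort(sample(nonsignal, n_ctrl)) else nonsignal
    if (design$contamination > 0 && design$n_signal > 0) {
      n_bad <- round(design$contamination * design$n_signal)
      if (n_bad > 0)
        control_ids <- c(control_ids, sample(truth$signal_ids, n_bad))
    }
    controls <- gene_set(control_ids, role = "negative")

    structure(list(Y = Y, truth = truth, controls = controls,
                   design = design),
              class = "coexpression_sim")
  })
}

# analytic correlation of the biological component (shared + idiosyncratic)
analytic_true_corr <- function(beta, idio_sd, gene_ids) {
  v <- colSums(beta^2) + idio_sd^2
  R <- crossprod(beta)
  nz <- v > 0
  scale <- ifelse(nz, sqrt(v), 1)
  R <- R / tcrossprod(scale)
  R[!nz, ] <- 0
  R[, !nz] <- 0
  diag(R) <- 1
  dimnames(R) <- list(gene_ids, gene_ids)
  R
}

#' @export
print.coexpression_sim <- function(x, ...) {
  cat("Simulated co-expression dataset\n")
  cat(sprintf("  Y: %d samples x %d genes; %d signal genes, %d negative controls\n",
              nrow(x$Y), ncol(x$Y), length(x$truth$signal_ids),
              length(x$controls)))
  cat(sprintf("  realized average |Cor(W, X)| = %.4f\n",
              x$truth$realized_cor_wx))
  invisible(x)
}

#' Analytic true gene-gene correlations of a simulation
#'
#' The correlation matrix of the biological component. For signal genes `i`,
#' `j` it is `(beta'beta)_{ij}` plus the idiosyncratic variance on the
#' diagonal, normalized to unit diagonal; it is 0 between a signal and a
#' non-signal gene and 0 among non-signal genes. When the idiosyncratic
#' component is zero this reduces to the normalized `beta'beta`.
#'
#' @param truth a `"simulation_truth"`.
#' @return a [correlation_set()] labelled `"truth"`.
#' @export
true_correlations <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  v <- colSums(truth$beta^2) + truth$idio_sd^2
  if (any(v[truth$signal_ids] == 0))
    stop("degenerate design: signal gene with zero biological variance")
  correlation_set(truth$true_corr, source_label = "truth",
                  m_samples = nrow(truth$X))
}

#' Realized dependence between unwanted variation and signal
#'
#' The mean absolute Pearson correlation over all (column of `W`, column of
#' `X`) pairs of the generated factor matrices. With `k_true = 0` there are
#' no pairs; 0 is returned with a note (empty-mean convention).
#'
#' @param truth a `"simulation_truth"`.
#' @return a single non-negative number.
#' @export
realized_noise_signal_correlation <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (ncol(truth$W) == 0 || ncol(truth$X) == 0) {
    message("no (W, X) factor column pairs; ",
            "returning 0 by the empty-mean convention")
    return(0)
  }
  mean(abs(stats::cor(truth$W, truth$X)))
}

#' Mixing coefficient for a target noise-signal correlation
#'
#' Inverts the (approximate) relation between the mixing coefficient `c` of
#' [simulation_design()] and the realized average `|Cor(W, X)|`. Each
#' correlation between a `W` column and an `X` column is approximately
#' normal with variance `c/p + 1/m` (mixing weight plus sampling noise), so
#' the mean absolute correlation is `sqrt(2/pi) * sqrt(c/p + 1/m)`; solving
#' for `c` gives the mix that realizes a desired dependence level.
#'
#' @param target_cor desired realized average `|Cor(W, X)|`.
#' @param n_blocks number of signal factors `p` in the design.
#' @param m number of samples.
#' @return the mixing coefficient `c`, clamped to `[0, 1)`.
#' @export
noise_signal_mix_for <- function(target_cor, n_blocks = 10, m = 180) {
  cc <- n_blocks * (pi / 2 * target_cor^2 - 1 / m)
  min(max(cc, 0), 1 - 1e-8)
}
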