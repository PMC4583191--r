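test_that("gene centering subtracts means, is idempotent, maps constants to zero", {
  Y <- cbind(g1 = c(1, 3), g2 = c(5, 5))
  rownames(Y) <- c("s1", "s2")
  Ys <- center_genes(Y)
  expect_equal(unname(Ys[, "g1"]), c(-1, 1))
  expect_equal(unname(Ys[, "g2"]), c(0, 0))
  expect_true(attr(Ys, "centered"))
  expect_equal(center_genes(Ys), Ys, ignore_attr = TRUE)

  set.seed(41)
  Y <- rand_expr(7, 5)
  Ys <- center_genes(Y)
  expect_lt(max(abs(colMeans(Ys))), 1e-10)
  expect_error(center_genes(Y[1, , drop = FALSE]), "at least 2 samples")
})

test_that("factor estimation recovers the control column space", {
  set.seed(42)
  # rank-1 controls: the single factor is the matrix's own direction
  u <- rnorm(8); u <- u - mean(u)
  Y <- outer(u, c(1, 2, -1, 0.5))
  colnames(Y) <- paste0("g", 1:4); rownames(Y) <- paste0("s", 1:8)
  Ys <- center_genes(Y)
  fit <- fit_unwanted_variation(Ys, colnames(Y), k = 1)
  expect_lt(principal_angle(fit$W, matrix(u)), 1e-8)

  # random 6 x 4 control block, k = 2: column space of W equals the top-2
  # eigenspace of the Gram matrix (independent eigendecomposition oracle)
  Ys <- center_genes(rand_expr(6, 4))
  fit <- fit_unwanted_variation(Ys, colnames(Ys), k = 2)
  ev <- eigen(tcrossprod(Ys), symmetric = TRUE)
  expect_lt(principal_angle(fit$W, ev$vectors[, 1:2]), 1e-6)
  # singular values consistent with Gram eigenvalues, non-increasing
  expect_equal(fit$singular_values^2, ev$values[1:4], tolerance = 1e-8)
  expect_true(all(diff(fit$singular_values) <= 1e-12))
  # orthonormal basis
  expect_lt(max(abs(crossprod(fit$U) - diag(2))), 1e-8)
})

test_that("factor estimation validates its inputs", {
  Ys <- center_genes(rand_expr(5, 6))
  expect_error(fit_unwanted_variation(Ys, colnames(Ys)[1:3], k = 4),
               "exceeds")
  expect_error(fit_unwanted_variation(rand_expr(5, 6), colnames(Ys), k = 1),
               "centered")
  Z <- center_genes(rand_expr(5, 6))
  Z[, 1:2] <- 0
  expect_error(fit_unwanted_variation(Z, colnames(Z)[1:2], k = 1),
               "degenerate")
})

test_that("ridge coefficients match the augmented least-squares oracle", {
  set.seed(43)
  for (i in 1:200) {
    m <- sample(4:9, 1); k <- sample(1:3, 1); n <- sample(2:6, 1)
    W <- matrix(rnorm(m * k), m, k)
    Ys <- center_genes(rand_expr(m, n))
    nu <- runif(1, 0.01, 5)
    fit <- structure(list(W = W, U = qr.Q(qr(W)), k = k, m = m,
                          singular_values = svd(W)$d,
                          control_ids = colnames(Ys)),
                     class = "ruv_fit")
    fit <- estimate_alpha_ridge(Ys, fit, nu)
    expect_equal(unname(fit$alpha), unname(ridge_oracle(W, Ys, nu)),
                 tolerance = 1e-8)
    # ridge normal equations hold
    resid_ne <- (crossprod(W) + nu * diag(k)) %*% fit$alpha - crossprod(W, Ys)
    expect_lt(max(abs(resid_ne)), 1e-8)
  }
})

test_that("ridge limits behave: nu = 0 with orthonormal basis, nu -> Inf", {
  set.seed(44)
  Ys <- center_genes(rand_expr(8, 5))
  fit <- fit_unwanted_variation(Ys, colnames(Ys)[1:4], k = 2)
  U <- fit$U
  fit_u <- fit; fit_u$W <- U
  fit_u <- estimate_alpha_ridge(Ys, fit_u, 0)
  expect_equal(unname(fit_u$alpha), unname(crossprod(U, Ys)), tolerance = 1e-12)

  # huge nu: alpha -> 0 and cleaning tends to the identity
  big <- 1e12 * fit$singular_values[1]^2
  fit_b <- estimate_alpha_ridge(Ys, fit, big)
  expect_lt(max(abs(fit_b$alpha)), 1e-9)
  expect_equal(remove_unwanted_variation(Ys, fit_b), Ys,
               tolerance = 1e-8, ignore_attr = TRUE)

  # max deviation from Y* decreases monotonically in nu past d1^2
  devs <- vapply(fit$singular_values[1]^2 * c(1, 10, 100, 1000), function(nu) {
    f <- estimate_alpha_ridge(Ys, fit, nu)
    max(abs(remove_unwanted_variation(Ys, f) - Ys))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("rank-deficient factors with nu = 0 raise a numerical-rank error", {
  Ys <- center_genes(rand_expr(6, 4))
  W <- matrix(rnorm(6), 6, 1)[, c(1, 1)]            # two identical columns
  fit <- structure(list(W = W, U = W, k = 2, m = 6,
                        singular_values = svd(W)$d,
                        control_ids = colnames(Ys)),
                   class = "ruv_fit")
  expect_error(estimate_alpha_ridge(Ys, fit, 0), "nu > 0")
})

test_that("removal cancels exactly when Y* lies in the control factor span", {
  set.seed(45)
  m <- 10; k <- 2; n <- 6
  W <- matrix(rnorm(m * k), m, k)
  W <- sweep(W, 2L, colMeans(W), "-")               # centered factors
  alpha <- matrix(rnorm(k * n), k, n)
  Y <- W %*% alpha
  dimnames(Y) <- list(paste0("s", 1:m), paste0("g", 1:n))
  Ys <- center_genes(Y)
  fit <- ruv_random(Ys, colnames(Y), k = k, nu = 0)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("k = 0 makes cleaning the identity on centered data", {
  set.seed(46)
  Y <- rand_expr(7, 5)
  fit <- ruv_random(Y, colnames(Y)[1:3], k = 0, nu = 1)
  expect_equal(residuals(fit), center_genes(Y), ignore_attr = TRUE)
  expect_equal(ncol(fit$W), 0)
  expect_equal(nrow(coef(fit)), 0)
})

test_that("cleaning output is always gene-centered", {
  set.seed(47)
  for (i in 1:5) {
    Y <- rand_expr(12, 20)
    fit <- ruv_random(Y, colnames(Y)[1:8], k = sample(0:3, 1))
    expect_lt(max(abs(colMeans(residuals(fit)))), 1e-10)
  }
})

test_that("cleaned negative controls approach the white-noise floor", {
  # Cor(W, X) = 0, true controls, correct k, small nu: residual control
  # variance should be close to Var(eps)
  ratios <- vapply(1:5, function(r) {
    sim <- small_sim(seed = 500 + r)
    fit <- ruv_random(sim$Y, sim$controls, k = sim$design$k_true)
    v <- apply(residuals(fit)[, sim$controls], 2L, var)
    mean(v) / sim$design$sigma_eps^2
  }, numeric(1))
  expect_lt(mean(ratios), 1.1)
})

test_that("the fit object reports its components coherently", {
  sim <- small_sim(seed = 7)
  fit <- ruv_random(sim$Y, sim$controls, k = 3, nu = 0.5)
  expect_s3_class(fit, "ruv_random")
  expect_equal(dim(fit$W), c(60, 3))
  expect_equal(dim(coef(fit)), c(3, 120))
  expect_equal(residuals(fit) + fitted(fit), fit$centered,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_gt(fit$var_removed, 0.3)   # noise-dominant regime
  expect_output(print(fit), "RUV-random")
  expect_output(print(summary(fit)), "singular values")
  expect_length(suggest_nu_grid(fit), 8)
  expect_equal(suggest_nu_grid(fit)[1], 0)
})

test_that("pure-noise null simulation cleans to near-zero mean correlation", {
  sim <- simulate_coexpression(simulation_design(
    n_signal = 0, n_blocks = 0, seed = 11))
  fit <- ruv_random(sim$Y, sim$controls, k = 3)
  R <- pearson_matrix(residuals(fit))
  expect_lt(abs(mean(R$corr[upper.tri(R$corr)])), 0.02)
})

test_that("cleaning collapses the Fisher-z error relative to raw data", {
  ratios <- vapply(1:3, function(r) {
    sim <- simulate_coexpression(simulation_design(seed = 600 + r))
    tc <- true_correlations(sim$truth)
    fit <- ruv_random(sim$Y, sim$controls, k = 3)
    fn_squared(pearson_matrix(residuals(fit)), tc) /
      fn_squared(pearson_matrix(sim$Y), tc)
  }, numeric(1))
  expect_lt(mean(ratios), 0.1)
})
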