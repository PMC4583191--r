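test_that("the null threshold matches the Fisher-z approximation on clean data", {
  # perfectly cleaned null data: threshold at the 0.99 quantile of |r| under
  # independence is approximately 2.58 / sqrt(m - 3)
  thr <- vapply(1:5, function(r) {
    sim <- simulate_coexpression(simulation_design(
      n_signal = 0, n_blocks = 0, seed = 1200 + r))
    fit <- ruv_random(sim$Y, sim$controls, k = 3)
    cfg <- prioritization_config(known = "gene_001", candidates = "gene_002",
                                 null_size = 400, seed = r)
    ct <- correlation_threshold(residuals(fit), cfg)
    expect_equal(ct$status, "ok")
    ct$threshold
  }, numeric(1))
  expect_equal(mean(thr), 2.5758 / sqrt(180 - 3), tolerance = 0.03)
})

test_that("degenerate and noise-saturated data yield non-ok statuses", {
  # all-identical genes: undefined
  Y <- matrix(rep(rnorm(20), 10), 20, 10,
              dimnames = list(paste0("s", 1:20), paste0("g", 1:10)))
  cfg <- prioritization_config(known = "g1", candidates = "g2", null_size = 10)
  ct <- correlation_threshold(Y + 0, cfg)
  expect_equal(ct$status, "undefined")
  expect_true(is.na(ct$threshold))

  # raw data with dominant shared noise: unreliable (null |r| median > 0.5)
  sim <- simulate_coexpression(simulation_design(
    k_true = 1, sigma_alpha = 6, seed = 1300))
  ct2 <- correlation_threshold(sim$Y, prioritization_config(
    known = "gene_001", candidates = "gene_002", null_size = 300, seed = 1))
  expect_equal(ct2$status, "unreliable")
  expect_output(print(ct2), "unreliable")
})

test_that("a candidate identical to a known gene is prioritized", {
  set.seed(61)
  Y <- rand_expr(40, 120)
  Y[, "g2"] <- Y[, "g1"] + rnorm(40, sd = 1e-3)
  cfg <- prioritization_config(known = "g1", candidates = c("g2", "g3"),
                               null_size = 100, min_links = 1, seed = 2)
  res <- prioritize_candidates(Y, cfg)
  expect_true(res$computable)
  tab <- res$table
  expect_true(tab$prioritized[tab$candidate == "g2"])
  expect_gt(tab$max_abs_r[tab$candidate == "g2"], 0.99)
  expect_output(print(res), "prioritized")
})

test_that("prioritization rejects overlapping or absent gene sets", {
  set.seed(62)
  Y <- rand_expr(10, 20)
  expect_error(prioritize_candidates(Y, prioritization_config("g1", "g1")),
               "overlap")
  expect_error(
    suppressMessages(prioritize_candidates(
      Y, prioritization_config("nope1", "g2"))),
    "no known")
  expect_error(prioritization_config("g1", "g2", null_quantile = 1),
               "null_quantile")
  expect_error(prioritization_config("g1", "g2", min_links = 0), "min_links")
})

test_that("pure-noise candidates are almost never prioritized", {
  # null candidates at m = 180 with min_links = 2: the false-prioritization
  # probability should be below 1%
  flags <- unlist(lapply(1:2, function(r) {
    sim <- simulate_coexpression(simulation_design(
      n_signal = 0, n_blocks = 0, seed = 1400 + r))
    fit <- ruv_random(sim$Y, sim$controls, k = 3)
    ids <- colnames(sim$Y)
    cfg <- prioritization_config(known = ids[1:5], candidates = ids[6:105],
                                 null_size = 300, min_links = 2, seed = r)
    res <- prioritize_candidates(residuals(fit), cfg)
    res$table$prioritized
  }))
  expect_length(flags, 200)
  expect_lt(mean(flags), 0.01)
})

test_that("candidates sharing a disease block are recovered after cleaning", {
  # disease-module scenario: a small fraction of the transcriptome carries
  # signal (so the random-gene null is genuinely mostly-uncorrelated, as on
  # a real array), and module genes are tightly co-regulated and robustly
  # expressed -- the positive-control idealisation of a disease network
  sens <- raw_sens <- numeric(5)
  for (r in 1:5) {
    sim <- simulate_coexpression(disease_module_design(seed = 1500 + r))
    blocks <- rep(1:2, each = 25)
    sig <- sim$truth$signal_ids
    known <- sig[blocks == 1][1:10]
    planted <- sig[blocks == 1][11:25]
    cfg <- prioritization_config(known = known, candidates = planted,
                                 null_size = 300, min_links = 2, seed = r)
    fit <- ruv_random(sim$Y, sim$controls, k = 3)
    res <- prioritize_candidates(residuals(fit), cfg)
    sens[r] <- mean(res$table$prioritized)
    raw <- prioritize_candidates(center_genes(sim$Y), cfg)
    raw_sens[r] <- if (raw$computable) mean(raw$table$prioritized) else 0
  }
  expect_gte(mean(sens), 0.9)
  # cleaning strictly helps when noise dominates
  expect_gt(mean(sens), mean(raw_sens))
})

test_that("prioritization is monotone in its thresholds and order-invariant", {
  sim <- small_sim(seed = 63)
  fit <- ruv_random(sim$Y, sim$controls, k = 3)
  Yc <- residuals(fit)
  blocks <- rep(1:6, each = 10)
  sig <- sim$truth$signal_ids
  known <- sig[blocks == 1][1:5]
  cands <- c(sig[blocks == 1][6:10], sig[blocks == 2][1:5])
  counts <- vapply(1:3, function(ml) {
    cfg <- prioritization_config(known, cands, null_size = 60,
                                 min_links = ml, seed = 3)
    prioritize_candidates(Yc, cfg)$n_prioritized
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  qs <- vapply(c(0.90, 0.99), function(q) {
    cfg <- prioritization_config(known, cands, null_size = 60,
                                 null_quantile = q, seed = 3)
    prioritize_candidates(Yc, cfg)$n_prioritized
  }, numeric(1))
  expect_gte(qs[1], qs[2])

  cfg_a <- prioritization_config(known, cands, null_size = 60, seed = 3)
  cfg_b <- prioritization_config(known, rev(cands), null_size = 60, seed = 3)
  ra <- prioritize_candidates(Yc, cfg_a)$table
  rb <- prioritize_candidates(Yc, cfg_b)$table
  expect_equal(ra, rb)
})

test_that("consistency reports count shared prioritized candidates", {
  mk <- function(cands, flagged, computable = TRUE) {
    structure(list(
      table = data.frame(candidate = cands, links = NA_integer_,
                         max_abs_r = NA_real_,
                         prioritized = cands %in% flagged),
      threshold = structure(list(threshold = 0.2,
                                 status = if (computable) "ok" else "unreliable",
                                 null_median = 0.1),
                            class = "correlation_threshold"),
      computable = computable,
      n_prioritized = sum(cands %in% flagged)),
      class = "prioritization_result")
  }
  u <- c("A", "B", "C", "D")
  rep3 <- list(mk(u, c("A", "B", "C")), mk(u, c("A", "B")), mk(u, c("A", "D")))
  cr <- consistency_report(rep3)
  expect_equal(cr$prioritized_in_all$ids, "A")
  expect_equal(cr$prioritized_in_all$count, 1)
  expect_equal(cr$by_min_studies$count, c(4, 2, 1))

  # identical results twice: shared count equals each input's count
  r1 <- mk(u, c("B", "C"))
  expect_equal(consistency_report(list(r1, r1))$prioritized_in_all$count, 2)

  # disjoint prioritized sets
  expect_equal(consistency_report(list(mk(u, "A"), mk(u, "B")))$
                 prioritized_in_all$count, 0)

  # non-computable results are dropped with a message
  expect_message(cr2 <- consistency_report(list(mk(u, "A"),
                                                mk(u, "B", computable = FALSE))),
                 "dropping")
  expect_equal(cr2$prioritized_in_all$ids, "A")

  expect_error(suppressMessages(consistency_report(
    list(mk(u, "A", computable = FALSE)))), "no computable")
  expect_error(consistency_report(list(mk(c("A"), "A"), mk(c("B"), "B"))),
               "shared")
})
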