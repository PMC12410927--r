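test_that("sampler configuration rejects impossible settings", {
  expect_error(sampler_config(n_iter = 1000, n_warmup = 1000), "smaller than")
  expect_error(sampler_config(n_iter = 1000, n_warmup = 2000), "smaller than")
  expect_error(sampler_config(n_chains = 0), "at least 1")
  cfg <- sampler_config()
  expect_equal(cfg$n_chains, 4L)
  expect_equal(cfg$n_iter, 6000L)
  expect_equal(cfg$n_warmup, 3000L)
})

test_that("classification applies the threshold, progenitor rule, and tie-break", {
  bp <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))
  colnames(bp) <- c("A", "B")
  cls <- classify_cells(bp, threshold = 0.7)
  expect_equal(cls$branch, c("A", "progenitor", "B"))
  expect_equal(cls$branch_index, c(1L, 0L, 2L))
  expect_equal(cls$p_max, c(0.9, 0.5, 0.8))

  # exact ties at the threshold go to the lowest branch index
  bp3 <- matrix(c(0.4, 0.4, 0.2), 1, dimnames = list(NULL, c("A", "B", "C")))
  cls3 <- classify_cells(bp3, threshold = 0.4)
  expect_equal(cls3$branch, "A")

  # a threshold at or below 1/K would assign every cell: rejected
  expect_error(classify_cells(bp, threshold = 0.5), "threshold")
  expect_error(classify_cells(bp, threshold = 1.2), "threshold")
})

test_that("fitting a symmetric panel warns about label non-identifiability", {
  panel <- suppressWarnings(marker_panel(c("A", "B"),
                                         list(g1 = c(1, 2), g2 = c(1, 2))))
  sim <- simulate_trajectory(15, panel, dropout_rate = 0, seed = 2)
  w <- capture_warnings(fit_trajectory(sim$expression, panel,
                                       config = sampler_config(n_chains = 2, n_iter = 60,
                                                               n_warmup = 30, seed = 1)))
  expect_true(any(grepl("unidentified", w)))
})

test_that("a small fit returns a complete, reproducible posterior object", {
  panel <- default_panel(2, 4)
  sim <- simulate_trajectory(30, panel, dropout_rate = 0.1, seed = 4)
  cfg <- sampler_config(n_chains = 2, n_iter = 300, n_warmup = 150, seed = 9)
  fit1 <- suppressWarnings(fit_trajectory(sim$expression, panel, config = cfg))
  fit2 <- suppressWarnings(fit_trajectory(sim$expression, panel, config = cfg))

  expect_identical(fit1$draws, fit2$draws)  # same seed, same draws
  expect_equal(nrow(fit1$draws), 2 * 150)
  expect_equal(ncol(fit1$draws), 30 + 1 + 7 * 8 + 2)
  expect_true(all(is.finite(fit1$lp)))
  expect_equal(dim(fit1$branch_prob), c(30L, 2L))
  expect_equal(unname(rowSums(fit1$branch_prob)), rep(1, 30), tolerance = 1e-8)
  expect_true(all(fit1$point$t >= 0 & fit1$point$t <= 1))
  expect_length(fit1$rhat, ncol(fit1$draws))
  expect_s3_class(fit1$point, "mixtraj_state")

  # an unnormalized matrix is refused
  raw <- expression_matrix(sim$expression$values)
  expect_error(fit_trajectory(raw, panel, config = cfg), "normalized")
})

test_that("pseudotime draws stay in the unit interval and pi draws on the simplex", {
  panel <- default_panel(2, 4)
  sim <- simulate_trajectory(20, panel, dropout_rate = 0.1, seed = 6)
  fit <- suppressWarnings(fit_trajectory(sim$expression, panel,
                                         config = sampler_config(n_chains = 2, n_iter = 200,
                                                                 n_warmup = 100, seed = 2)))
  tdraws <- fit$draws[, grep("^t\\[", colnames(fit$draws))]
  expect_true(all(tdraws > 0 & tdraws < 1))
  pidraws <- fit$draws[, grep("^pi\\[", colnames(fit$draws)), drop = FALSE]
  expect_true(all(pidraws > 0 & pidraws < 1))
})

test_that("a single-lineage fit recovers the ordering of linear synthetic data", {
  # with K = 1 the mixture collapses to a linear generative model:
  # every marker is switch-like and pseudotime is identified by the cascade
  panel <- default_panel(1, 4)
  sim <- simulate_trajectory(60, panel, dropout_rate = 0.1, seed = 3)
  fit <- suppressWarnings(fit_trajectory(
    sim$expression, panel,
    config = sampler_config(n_chains = 2, n_iter = 1500, n_warmup = 750, seed = 3)))
  rho <- cor(pseudotime(fit), sim$true_time, method = "spearman")
  expect_gte(abs(rho), 0.8)
  expect_lt(max(fit$rhat, na.rm = TRUE), 1.05)
})

test_that("half-sample mode finds the dominant mode of a skewed mixture", {
  set.seed(15)
  x <- c(rnorm(800, 0), rnorm(200, 6))
  expect_equal(half_sample_mode(x), 0, tolerance = 0.3)
  expect_equal(half_sample_mode(c(2, 2, 2, 9)), 2)
  expect_equal(half_sample_mode(c(5)), 5)
})
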