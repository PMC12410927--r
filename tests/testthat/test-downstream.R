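test_that("differentiation potential is the Shannon entropy of branch probabilities", {
  expect_equal(unname(differentiation_potential(matrix(c(1, 0, 0), 1))), 0)
  expect_equal(unname(differentiation_potential(matrix(rep(1 / 3, 3), 1))), log(3))
  expect_equal(unname(differentiation_potential(matrix(rep(1 / 3, 3), 1))), 1.098612,
               tolerance = 1e-6)
  expect_equal(unname(differentiation_potential(matrix(c(0.5, 0.5), 1))), log(2))
  expect_equal(unname(differentiation_potential(matrix(c(0.5, 0.5), 1), base = 2)), 1)
  expect_error(differentiation_potential(matrix(c(0.6, 0.6), 1)), "simplex")
})

test_that("entropy is concave over the simplex", {
  set.seed(13)
  for (r in 1:50) {
    K <- sample(2:4, 1)
    p <- rgamma(K, 1); p <- p / sum(p)
    q <- rgamma(K, 1); q <- q / sum(q)
    lam <- runif(1)
    mix <- lam * p + (1 - lam) * q
    dp <- function(v) unname(differentiation_potential(matrix(v, 1)))
    expect_gte(dp(mix) + 1e-12, lam * dp(p) + (1 - lam) * dp(q))
  }
})

test_that("single-draw branch responsibilities follow Bayes rule", {
  expect_equal(branch_responsibility(c(0.3, 0.1), c(0.5, 0.5)), c(0.75, 0.25))
  M <- branch_responsibility(matrix(c(0.3, 0.2, 0.1, 0.2), 2), c(0.5, 0.5))
  expect_equal(rowSums(M), c(1, 1))
})

test_that("gene tests reject degenerate inputs", {
  expect_error(test_branch_gene(rnorm(5), runif(5)), "too few cells")
  expect_error(test_branch_gene(rnorm(20), rep(0.5, 20)), "degenerate")
  expect_error(test_branch_gene(rnorm(20), runif(20, 0.5, 1.5)), "\\[0,1\\]")
  expect_error(test_branch_gene(rnorm(20), runif(10)), "equal length")
})

test_that("a flat gene favours the constant model, a clean switch the sigmoid model", {
  set.seed(19)
  t <- runif(50)
  flat <- test_branch_gene(rnorm(50, 0.5, 0.05), t, gene_id = "flat", seed = 2)
  expect_lte(flat$bf10, 1)
  expect_equal(flat$evidence, "null")

  y <- sigmoid_mean(t, 0.5, 20, 0.5) + rnorm(50, 0, 0.05)
  dyn <- test_branch_gene(pmax(y, 0), t, gene_id = "dyn", seed = 2)
  expect_gt(dyn$bf10, 10)
  expect_equal(dyn$evidence, "strong")
  expect_equal(unname(dyn$m1_params["delta"]), 0.5, tolerance = 0.2)
  expect_equal(dyn$activation_time, 0.5, tolerance = 0.15)
})

test_that("the Bayes factor is the exponentiated marginal-likelihood gap", {
  set.seed(29)
  t <- runif(30)
  r <- test_branch_gene(rnorm(30, 0.4, 0.1), t, seed = 3)
  expect_equal(r$bf10, exp(r$log_marginal_M1 - r$log_marginal_M0), tolerance = 1e-12)
  expect_gt(r$bf10, 0)
})

test_that("the M0 marginal likelihood matches 2-D quadrature", {
  set.seed(37)
  y <- rnorm(12, 0.5, 0.1)
  f <- mixtraj:::.fit_curve_model(y, runif(12), 0L,
                                  list(mu = c(0.5, 0.5), sigma_scale = 0.5),
                                  n_chains = 2, n_iter = 2000, n_warmup = 500)
  # independent oracle: integrate the joint over (mu, sigma) on the
  # constrained scale with proper truncated-normal and half-normal priors
  joint <- function(mu, sig) {
    pri <- dnorm(mu, 0.5, 0.5) / pnorm(0.5 / 0.5) *
      2 * dnorm(sig, 0, 0.5)
    lik <- exp(colSums(matrix(dnorm(rep(y, length(mu)),
                                    rep(mu, each = length(y)),
                                    rep(sig, each = length(y)), log = TRUE),
                              length(y))))
    pri * lik
  }
  grid_ml <- integrate(function(sig) {
    vapply(sig, function(s)
      integrate(function(mu) joint(mu, rep(s, length(mu))), 0, 4,
                rel.tol = 1e-9)$value, numeric(1))
  }, 1e-6, 4, rel.tol = 1e-8)$value
  expect_equal(f$log_ml, log(grid_ml), tolerance = 0.05)
})

test_that("ranking takes top Bayes factors then orders by activation time", {
  mk <- function(g, bf, t0) list(gene_id = g, branch = "A", bf10 = bf,
                                 evidence = "strong", activation_time = t0)
  res <- list(mk("g1", 100, 0.2), mk("g2", 5, 0.9), mk("g3", 50, 0.5), mk("g4", 30, 0.1))
  top1 <- rank_by_activation(res, top_n = 1)
  expect_equal(top1$gene_id, "g1")

  top3 <- rank_by_activation(res, top_n = 3)
  expect_equal(top3$gene_id, c("g4", "g1", "g3"))  # by t0 among the top-3 BFs

  # ties on both keys break lexicographically by gene id
  tie <- list(mk("gb", 10, 0.3), mk("ga", 10, 0.3), mk("gc", 10, 0.3))
  expect_equal(rank_by_activation(tie, top_n = 3)$gene_id, c("ga", "gb", "gc"))
  expect_error(rank_by_activation(list()), "empty")
})
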