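test_that("mean curves hit their closed-form landmarks", {
  # logistic midpoint: at t = t0 the switch sits at half its ceiling, delta
  expect_equal(sigmoid_mean(0.3, delta = 0.7, tau = 12, t0 = 0.3), 0.7)
  # saturation limits
  expect_equal(sigmoid_mean(1e6, 0.5, 10, 0.5), 1, tolerance = 1e-12)
  expect_equal(sigmoid_mean(-1e6, 0.5, 10, 0.5), 0, tolerance = 1e-12)
  expect_equal(sigmoid_mean(0.6, 0.5, 10, 0.5), 1 / (1 + exp(-1)), tolerance = 1e-9)
  expect_equal(sigmoid_mean(0.6, 0.5, 10, 0.5), 0.731059, tolerance = 1e-6)

  # pulse peak 2*eta at midpoint; zero-width pulse degenerates to a constant
  expect_equal(pulse_mean(0.4, eta = 0.3, zeta = 50, t0 = 0.4), 0.6)
  expect_equal(pulse_mean(c(0, 0.5, 1), 0.3, 0, 0.5), rep(0.6, 3))
  expect_equal(pulse_mean(0.6, 0.5, 100, 0.5), exp(-1), tolerance = 1e-9)
  expect_equal(round(pulse_mean(0.6, 0.5, 100, 0.5), 6), 0.367879)
})

test_that("variance has the 0.01 floor and is monotone in mean and dispersion", {
  expect_equal(variance_fn(0, 0), 0.01)
  expect_equal(variance_fn(0, 5), 0.01)
  expect_equal(variance_fn(1, 0), 1.01)
  expect_equal(variance_fn(0.5, 1), 1.01)
  mus <- seq(0, 2, by = 0.1)
  expect_true(all(diff(variance_fn(mus, 0.3)) > 0))
  phis <- seq(0, 3, by = 0.1)
  expect_true(all(diff(variance_fn(0.5, phis)) > 0))
  expect_error(variance_fn(-0.1, 0), "non-negative")
  expect_error(variance_fn(0.1, -1), "non-negative")
})

test_that("dropout probability is the inverse logit, overflow-safe, monotone with sign of slope", {
  expect_equal(dropout_prob(0.5, 0, 0), 0.5)
  expect_equal(dropout_prob(0.5, 1, -2), 0.5)
  expect_equal(dropout_prob(0, -1e8, 0), 0)
  expect_equal(dropout_prob(0, 1e8, 0), 1)
  mus <- seq(0, 1, by = 0.05)
  expect_true(all(diff(dropout_prob(mus, 0, -5)) < 0))
  expect_true(all(diff(dropout_prob(mus, 0, 5)) > 0))
})

test_that("zero observations mix a point mass with the Gaussian density", {
  expect_equal(gene_loglik(0, mu = 0.5, sigma2 = 0.02, p_drop = 1), 0)     # certain dropout absorbs zeros
  expect_equal(gene_loglik(0.4, 0.5, 0.02, 1), -Inf)                       # nonzero impossible then
  expect_equal(gene_loglik(0.4, 0.4, 0.01, 0), -0.5 * log(2 * pi * 0.01), tolerance = 1e-12)
  expect_equal(gene_loglik(0.4, 0.4, 0.01, 0), 1.383647, tolerance = 1e-6)
  # mixture at zero: p + (1-p) N(0; mu, s2)
  p <- 0.3; mu <- 0.2; s2 <- 0.05
  expect_equal(gene_loglik(0, mu, s2, p), log(p + (1 - p) * dnorm(0, mu, sqrt(s2))))
  expect_error(gene_loglik(0.1, 0.1, 0, 0.5), "positive")
})

test_that("pulse is symmetric about its midpoint and sigmoid monotone in t", {
  for (d in seq(0.05, 0.4, by = 0.05))
    expect_equal(pulse_mean(0.5 + d, 0.4, 30, 0.5), pulse_mean(0.5 - d, 0.4, 30, 0.5))
  tt <- seq(0, 1, by = 0.02)
  expect_true(all(diff(sigmoid_mean(tt, 0.5, 8, 0.4)) > 0))
  expect_true(all(diff(sigmoid_mean(tt, 0.5, -8, 0.4)) < 0))
})

test_that("cell likelihood collapses correctly for K = 1 and exchangeable branches", {
  set.seed(11)
  toy <- random_toy(N = 1, G = 3, K = 1)
  y <- toy$expr$values[1, ]
  M <- mixtraj:::.marker_matrix(toy$panel, toy$state$dynamics$gene)
  mu <- ifelse(M[, 1] == 1, sigmoid_mean(toy$state$t[1], toy$state$dynamics$delta,
                                         toy$state$dynamics$tau, toy$state$dynamics$t0_switch),
               pulse_mean(toy$state$t[1], toy$state$dynamics$eta,
                          toy$state$dynamics$zeta, toy$state$dynamics$t0_pulse))
  s2 <- variance_fn(mu, toy$state$phi)
  p <- dropout_prob(mu, toy$state$beta0, toy$state$beta1)
  expect_equal(cell_loglik(y, toy$state$t[1], toy$state, toy$panel),
               sum(gene_loglik(y, mu, s2, p)))

  # identical dynamics across branches: mixture equals the single branch value
  panel2 <- suppressWarnings(marker_panel(c("A", "B"), list(g1 = c(1, 2), g2 = c(1, 2), g3 = c(1, 2))))
  st <- toy$state
  st$pi <- c(0.31, 0.69)
  ll2 <- cell_loglik(y, st$t[1], st, panel2)
  panel1 <- suppressWarnings(marker_panel("A", list(g1 = 1, g2 = 1, g3 = 1)))
  st1 <- st; st1$pi <- 1
  expect_equal(ll2, cell_loglik(y, st$t[1], st1, panel1), tolerance = 1e-12)
})

test_that("marginalized likelihood equals exhaustive enumeration over latents", {
  set.seed(23)
  for (r in 1:40) {
    toy <- random_toy()
    for (i in seq_len(nrow(toy$expr$values))) {
      ll <- cell_loglik(toy$expr$values[i, ], toy$state$t[i], toy$state, toy$panel)
      oracle <- enumerate_cell_lik(toy$expr$values[i, ], toy$state$t[i], toy$state, toy$panel)
      expect_equal(ll, oracle, tolerance = 1e-10)
    }
  }
})

test_that("the observation density integrates to one (point mass at zero included)", {
  set.seed(5)
  toy <- random_toy(N = 1, G = 1, K = 2)
  st <- toy$state
  dens <- function(y) vapply(y, function(yy)
    exp(cell_loglik(yy, st$t[1], st, toy$panel)), numeric(1))
  # continuous part: integrate the nonzero-branch density over the real line
  cont <- integrate(dens, -10, 10, subdivisions = 500, rel.tol = 1e-8)$value
  # the atom at zero: total mass at y=0 minus the continuous density there
  atom <- exp(cell_loglik(0, st$t[1], st, toy$panel)) - dens(1e-300)
  expect_equal(cont + atom, 1, tolerance = 1e-3)
})

test_that("joint likelihood is additive over cells and zero for an empty matrix", {
  set.seed(31)
  toy <- random_toy(N = 3, G = 2, K = 2)
  per_cell <- vapply(1:3, function(i)
    cell_loglik(toy$expr$values[i, ], toy$state$t[i], toy$state, toy$panel), numeric(1))
  expect_equal(joint_loglik(toy$expr, toy$state, toy$panel), sum(per_cell))

  # duplicating a cell (and its pseudotime) doubles its contribution exactly
  e2 <- expression_matrix(toy$expr$values[c(1, 1, 2, 3), ],
                          c("c1a", "c1b", "c2", "c3"), toy$expr$gene_ids, normalized = TRUE)
  st2 <- toy$state
  st2$t <- toy$state$t[c(1, 1, 2, 3)]
  expect_equal(joint_loglik(e2, st2, toy$panel),
               sum(per_cell) + per_cell[1], tolerance = 1e-12)

  empty <- expression_matrix(matrix(numeric(0), 0, 2, dimnames = list(NULL, toy$expr$gene_ids)),
                             character(0), toy$expr$gene_ids, normalized = TRUE)
  st0 <- toy$state
  st0$t <- numeric(0)
  expect_equal(joint_loglik(empty, st0, toy$panel), 0)
  expect_error(joint_loglik(expression_matrix(toy$expr$values), toy$state, toy$panel),
               "normalized")
})

test_that("log prior matches hand-evaluated densities and respects support", {
  toy <- local({ set.seed(3); random_toy(N = 2, G = 2, K = 2) })
  st <- toy$state
  st_bad <- st
  st_bad$t[1] <- 1.5
  expect_identical(log_prior(st_bad), -Inf)

  # Dirichlet(1/2, 1/2) at (0.5, 0.5): log(2/pi)
  pr <- prior_spec(dirichlet_alpha = 0.5)
  dir_term <- lgamma(1) - 2 * lgamma(0.5) - 0.5 * log(0.25)
  expect_equal(dir_term, -0.451583, tolerance = 1e-6)
  st_even <- st
  st_even$pi <- c(0.5, 0.5)
  st_odd <- st
  st_odd$pi <- c(0.3, 0.7)
  dir_odd <- lgamma(1) - 2 * lgamma(0.5) - 0.5 * log(0.3 * 0.7)
  expect_equal(log_prior(st_even, pr) - log_prior(st_odd, pr), dir_term - dir_odd,
               tolerance = 1e-9)

  # full value against an independent per-term density sum
  h <- mixtraj:::.expand_priors(prior_spec(), st$dynamics$gene, 2)
  tn <- function(x, m, s) dnorm(x, m, s, log = TRUE) - pnorm(m / s, log.p = TRUE)
  manual <- lgamma(2 * h$alpha) - 2 * lgamma(h$alpha) + (h$alpha - 1) * sum(log(st$pi)) +
    sum(tn(st$dynamics$delta, h$d_m, h$d_s)) +
    sum(dnorm(st$dynamics$tau, h$tau_m, h$tau_s, log = TRUE)) +
    sum(dbeta(st$dynamics$t0_switch, h$t0s_a, h$t0s_b, log = TRUE)) +
    sum(tn(st$dynamics$eta, h$e_m, h$e_s)) +
    sum(tn(st$dynamics$zeta, h$z_m, h$z_s)) +
    sum(dbeta(st$dynamics$t0_pulse, h$t0p_a, h$t0p_b, log = TRUE)) +
    sum(dgamma(st$phi, shape = h$phi_a, rate = h$phi_b, log = TRUE)) +
    dnorm(st$beta0, h$b_m, h$b_s, log = TRUE) + dnorm(st$beta1, h$b_m, h$b_s, log = TRUE)
  expect_equal(log_prior(st, prior_spec()), manual, tolerance = 1e-10)
})

test_that("the sampler's C++ log posterior equals prior + likelihood + Jacobian", {
  set.seed(99)
  panel <- suppressWarnings(default_panel(2, 2))
  genes <- names(panel$marker_map)
  Y <- matrix(abs(rnorm(12, 0.4, 0.3)), 3, 4)
  Y[c(2, 7)] <- 0
  expr <- expression_matrix(Y, paste0("c", 1:3), genes, normalized = TRUE)
  priors <- prior_spec()
  data <- mixtraj:::.model_data(expr, panel, priors)
  for (r in 1:30) {
    st <- mixtraj:::.draw_state_from_priors(3, genes, 2, priors)
    u <- mixtraj:::.state_to_u(st)
    lp_cpp <- mixtraj:::cpp_mix_lp_grad(u, data)$lp
    lp_r <- log_prior(st, priors) + joint_loglik(expr, st, panel) + mixtraj:::.log_jacobian(st)
    expect_equal(lp_cpp, lp_r, tolerance = 1e-8)
  }
})

test_that("C++ gradients match finite differences", {
  set.seed(17)
  panel <- suppressWarnings(default_panel(2, 2))
  genes <- names(panel$marker_map)
  Y <- matrix(abs(rnorm(8, 0.4, 0.3)), 2, 4)
  Y[3] <- 0
  expr <- expression_matrix(Y, paste0("c", 1:2), genes, normalized = TRUE)
  data <- mixtraj:::.model_data(expr, panel, prior_spec())
  st <- mixtraj:::.draw_state_from_priors(2, genes, 2, prior_spec())
  u <- mixtraj:::.state_to_u(st)
  res <- mixtraj:::cpp_mix_lp_grad(u, data)
  h <- 1e-6
  gnum <- vapply(seq_along(u), function(i) {
    up <- u; up[i] <- up[i] + h
    um <- u; um[i] <- um[i] - h
    (mixtraj:::cpp_mix_lp_grad(up, data)$lp - mixtraj:::cpp_mix_lp_grad(um, data)$lp) / (2 * h)
  }, numeric(1))
  expect_equal(res$grad, gnum, tolerance = 1e-5)
})
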