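#' Switch-like logistic mean curve
#'
#' Mean expression of a marker gene along the branch it marks:
#' `mu(t) = 2*delta / (1 + exp(-tau*(t - t0)))`. At `t = t0` the curve is at
#' half its saturating level, i.e. exactly `delta`.
#'
#' @param t pseudotime in \[0,1\] (vectorized).
#' @param delta maximal amplitude (the curve saturates at `2*delta`).
#' @param tau activation steepness; negative values encode switch-off.
#' @param t0 activation time in \[0,1\].
#' @return Mean expression, same length as the longest argument.
#' @export
sigmoid_mean <- function(t, delta, tau, t0) {
  2 * delta * stats::plogis(tau * (t - t0))
}

#' Transient Gaussian pulse mean curve
#'
#' Mean expression of a gene on branches it does not mark:
#' `mu(t) = 2*eta * exp(-zeta*(t - t0)^2)`, peaking at `2*eta` when `t = t0`.
#'
#' @param t pseudotime in \[0,1\] (vectorized).
#' @param eta peak half-height (the pulse tops out at `2*eta`).
#' @param zeta pulse width (inverse squared scale), `>= 0`.
#' @param t0 pulse midpoint in \[0,1\].
#' @export
pulse_mean <- function(t, eta, zeta, t0) {
  2 * eta * exp(-zeta * (t - t0)^2)
}

#' Mean-dependent overdispersed variance
#'
#' `Var = (1 + phi) * mu + epsilon`, with `epsilon = 0.01` a small constant
#' for numerical stability, so the variance never falls below 0.01 and grows
#' with both the mean and the gene-wise dispersion.
#'
#' @param mu mean expression, `>= 0`.
#' @param phi gene-wise dispersion, `>= 0`.
#' @param epsilon stability floor, fixed at 0.01 by default.
#' @export
variance_fn <- function(mu, phi, epsilon = 0.01) {
  if (any(mu < 0)) stop("`mu` must be non-negative")
  if (any(phi < 0)) stop("`phi` must be non-negative")
  (1 + phi) * mu + epsilon
}

#' Dropout probability
#'
#' Probability that a transcript goes undetected, as a function of the
#' expected expression: `p = plogis(beta0 + beta1 * mu)`. A negative slope
#' `beta1` makes highly expressed genes less likely to drop out.
#'
#' @param mu mean expression.
#' @param beta0,beta1 global dropout intercept and slope.
#' @export
dropout_prob <- function(mu, beta0, beta1) {
  stats::plogis(beta0 + beta1 * mu)
}

#' Zero-inflated per-gene log density
#'
#' Observation density for a single gene with the dropout indicator
#' marginalized out. An exact zero contributes
#' `p_drop + (1 - p_drop) * N(0; mu, sigma2)` (point mass plus the
#' continuous density evaluated at zero, the standard zero-inflation
#' convention); a nonzero value contributes
#' `(1 - p_drop) * N(y; mu, sigma2)`.
#'
#' @param y observed expression (vectorized).
#' @param mu,sigma2 mean and variance of the detected component; `sigma2 > 0`.
#' @param p_drop dropout probability in \[0,1\].
#' @return Log density, `-Inf` where the observation is impossible.
#' @export
gene_loglik <- function(y, mu, sigma2, p_drop) {
  if (any(sigma2 <= 0)) stop("`sigma2` must be strictly positive")
  if (any(p_drop < 0 | p_drop > 1)) stop("`p_drop` must lie in [0,1]")
  n <- max(length(y), length(mu), length(sigma2), length(p_drop))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  sigma2 <- rep_len(sigma2, n); p_drop <- rep_len(p_drop, n)
  out <- numeric(n)
  z <- y == 0
  if (any(z))
    out[z] <- log(p_drop[z] + (1 - p_drop[z]) * stats::dnorm(0, mu[z], sqrt(sigma2[z])))
  if (any(!z))
    out[!z] <- log1p(-p_drop[!z]) + stats::dnorm(y[!z], mu[!z], sqrt(sigma2[!z]), log = TRUE)
  out
}

#' Per-branch mean matrix for one cell
#'
#' @noRd
.branch_means <- function(t, dynamics, marker_col) {
  ifelse(marker_col == 1L,
         sigmoid_mean(t, dynamics$delta, dynamics$tau, dynamics$t0_switch),
         pulse_mean(t, dynamics$eta, dynamics$zeta, dynamics$t0_pulse))
}

#' Model state
#'
#' One full parameter configuration of the generative model: per-cell
#' pseudotimes, lineage proportions, per-gene dynamic parameters, gene-wise
#' dispersion, and the global dropout coefficients.
#'
#' @param t length-N pseudotimes in \[0,1\].
#' @param pi length-K simplex of lineage proportions.
#' @param dynamics data.frame with columns `gene`, `delta`, `tau`,
#'   `t0_switch`, `eta`, `zeta`, `t0_pulse` (one row per gene). Switch
#'   parameters apply on branches the gene marks, pulse parameters
#'   elsewhere.
#' @param phi length-G gene dispersions, `>= 0`.
#' @param beta0,beta1 global dropout coefficients.
#' @return An object of class `mixtraj_state`.
#' @export
model_state <- function(t, pi, dynamics, phi, beta0, beta1) {
  if (any(t < 0 | t > 1)) stop("pseudotimes must lie in [0,1]")
  if (abs(sum(pi) - 1) > 1e-12 || any(pi < 0)) stop("`pi` must be a simplex (sums to 1 within 1e-12)")
  need <- c("gene", "delta", "tau", "t0_switch", "eta", "zeta", "t0_pulse")
  if (!all(need %in% names(dynamics))) stop("`dynamics` must have columns ", paste(need, collapse = ", "))
  if (any(dynamics$delta < 0)) stop("switch amplitudes `delta` must be non-negative")
  if (any(dynamics$eta < 0) || any(dynamics$zeta < 0)) stop("pulse `eta` and `zeta` must be non-negative")
  if (any(dynamics$t0_switch < 0 | dynamics$t0_switch > 1) ||
      any(dynamics$t0_pulse < 0 | dynamics$t0_pulse > 1)) stop("activation times must lie in [0,1]")
  if (length(phi) != nrow(dynamics)) stop("`phi` must have one entry per gene")
  if (any(phi < 0)) stop("`phi` must be non-negative")
  structure(list(t = as.numeric(t), pi = as.numeric(pi),
                 dynamics = as.data.frame(dynamics), phi = as.numeric(phi),
                 beta0 = as.numeric(beta0), beta1 = as.numeric(beta1)),
            class = "mixtraj_state")
}

#' Mixture log-likelihood of one cell
#'
#' Marginalizes the latent branch assignment:
#' `log p(y | t, pi, Theta) = logsumexp_k [ log pi_k + sum_j log p_k(y_j) ]`,
#' computed with log-sum-exp so it does not underflow for panels of up to a
#' few hundred genes.
#'
#' @param y length-G expression vector (normalized scale).
#' @param t the cell's pseudotime.
#' @param state a [model_state()] whose dynamics rows align with `panel`'s
#'   gene order.
#' @param panel a [marker_panel()].
#' @param epsilon variance stability floor.
#' @return Scalar log-likelihood.
#' @export
cell_loglik <- function(y, t, state, panel, epsilon = 0.01) {
  stopifnot(inherits(state, "mixtraj_state"), inherits(panel, "mixtraj_panel"))
  G <- nrow(state$dynamics)
  if (length(y) != G) stop("`y` length does not match the number of genes in `state`")
  if (length(state$pi) != panel$K) stop("`state$pi` length does not match panel K")
  M <- .marker_matrix(panel, state$dynamics$gene)
  lk <- vapply(seq_len(panel$K), function(k) {
    mu <- .branch_means(t, state$dynamics, M[, k])
    s2 <- variance_fn(mu, state$phi, epsilon)
    p <- dropout_prob(mu, state$beta0, state$beta1)
    log(state$pi[k]) + sum(gene_loglik(y, mu, s2, p))
  }, numeric(1))
  m <- max(lk)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lk - m)))
}

#' Joint log-likelihood of a dataset
#'
#' Cells are conditionally independent given their pseudotimes, so the joint
#' log-likelihood is the sum of [cell_loglik()] over cells (0 for an empty
#' matrix).
#'
#' @param m a normalized `mixtraj_expr`.
#' @param state a [model_state()] with one pseudotime per cell.
#' @param panel a [marker_panel()].
#' @param epsilon variance stability floor.
#' @export
joint_loglik <- function(m, state, panel, epsilon = 0.01) {
  stopifnot(inherits(m, "mixtraj_expr"))
  if (!m$normalized) stop("`m` must be normalized (model scale); run normalize_expression()")
  N <- nrow(m$values)
  if (length(state$t) != N) stop("`state$t` must have one pseudotime per cell")
  if (N == 0) return(0)
  sum(vapply(seq_len(N), function(i)
    cell_loglik(m$values[i, ], state$t[i], state, panel, epsilon), numeric(1)))
}

#' Log prior density of a model state
#'
#' Sum of the component log priors: uniform pseudotimes, symmetric Dirichlet
#' lineage proportions, truncated-normal amplitudes, normal steepness, Beta
#' activation times, Gamma dispersion, and normal dropout coefficients.
#' Returns `-Inf` outside the support. Truncated-normal components are
#' properly renormalized.
#'
#' @param state a [model_state()].
#' @param priors a [prior_spec()].
#' @return Scalar log density.
#' @export
log_prior <- function(state, priors = prior_spec()) {
  stopifnot(inherits(state, "mixtraj_state"))
  K <- length(state$pi)
  dyn <- state$dynamics
  h <- .expand_priors(priors, dyn$gene, K)
  if (any(state$t < 0 | state$t > 1)) return(-Inf)
  if (any(dyn$delta < 0) || any(dyn$eta < 0) || any(dyn$zeta < 0) || any(state$phi < 0)) return(-Inf)
  if (any(dyn$t0_switch < 0 | dyn$t0_switch > 1) || any(dyn$t0_pulse < 0 | dyn$t0_pulse > 1)) return(-Inf)
  if (abs(sum(state$pi) - 1) > 1e-12 || any(state$pi < 0)) return(-Inf)
  # Dirichlet(alpha, ..., alpha)
  lp <- lgamma(K * h$alpha) - K * lgamma(h$alpha) + (h$alpha - 1) * sum(log(state$pi))
  tnorm <- function(x, m, s) stats::dnorm(x, m, s, log = TRUE) - stats::pnorm(m / s, log.p = TRUE)
  lp <- lp +
    sum(tnorm(dyn$delta, h$d_m, h$d_s)) +
    sum(stats::dnorm(dyn$tau, h$tau_m, h$tau_s, log = TRUE)) +
    sum(stats::dbeta(dyn$t0_switch, h$t0s_a, h$t0s_b, log = TRUE)) +
    sum(tnorm(dyn$eta, h$e_m, h$e_s)) +
    sum(tnorm(dyn$zeta, h$z_m, h$z_s)) +
    sum(stats::dbeta(dyn$t0_pulse, h$t0p_a, h$t0p_b, log = TRUE)) +
    sum(stats::dgamma(state$phi, shape = h$phi_a, rate = h$phi_b, log = TRUE)) +
    stats::dnorm(state$beta0, h$b_m, h$b_s, log = TRUE) +
    stats::dnorm(state$beta1, h$b_m, h$b_s, log = TRUE)
  lp
}
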