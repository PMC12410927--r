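# Mapping between a constrained model state and the sampler's unconstrained
# parameter vector. Layout (0-based offsets as in the C++ core):
#   [1..N]               logit pseudotimes
#   [N+1..N+K-1]         additive log-ratio coordinates of pi (last branch ref)
#   per gene j, 6 slots: log delta, tau, logit t0_switch,
#                        log eta, log zeta, logit t0_pulse
#   [.. + G]             log phi per gene
#   last two             beta0, beta1

.param_layout <- function(N, G, K) {
  list(N = N, G = G, K = K, P = N + (K - 1) + 7L * G + 2L,
       t = seq_len(N),
       pi = if (K > 1) N + seq_len(K - 1) else integer(0),
       dyn = function(j) N + (K - 1) + 6L * (j - 1L) + 1:6,
       phi = N + (K - 1) + 6L * G + seq_len(G),
       beta = N + (K - 1) + 7L * G + 1:2)
}

.state_to_u <- function(state) {
  N <- length(state$t); G <- nrow(state$dynamics); K <- length(state$pi)
  lay <- .param_layout(N, G, K)
  u <- numeric(lay$P)
  u[lay$t] <- stats::qlogis(pmin(pmax(state$t, 1e-12), 1 - 1e-12))
  if (K > 1) u[lay$pi] <- log(state$pi[-K] / state$pi[K])
  for (j in seq_len(G)) {
    d <- state$dynamics[j, ]
    u[lay$dyn(j)] <- c(log(d$delta), d$tau,
                       stats::qlogis(pmin(pmax(d$t0_switch, 1e-12), 1 - 1e-12)),
                       log(d$eta), log(d$zeta),
                       stats::qlogis(pmin(pmax(d$t0_pulse, 1e-12), 1 - 1e-12)))
  }
  u[lay$phi] <- log(state$phi)
  u[lay$beta] <- c(state$beta0, state$beta1)
  u
}

.u_to_state <- function(u, gene_ids, K) {
  G <- length(gene_ids)
  N <- length(u) - (K - 1) - 7L * G - 2L
  lay <- .param_layout(N, G, K)
  t <- stats::plogis(u[lay$t])
  if (K > 1) {
    e <- exp(c(u[lay$pi], 0) - max(c(u[lay$pi], 0)))
    pi <- e / sum(e)
  } else pi <- 1
  dyn <- do.call(rbind, lapply(seq_len(G), function(j) {
    v <- u[lay$dyn(j)]
    data.frame(gene = gene_ids[j], delta = exp(v[1]), tau = v[2],
               t0_switch = stats::plogis(v[3]), eta = exp(v[4]),
               zeta = exp(v[5]), t0_pulse = stats::plogis(v[6]))
  }))
  model_state(t, pi, dyn, phi = exp(u[lay$phi]),
              beta0 = u[lay$beta[1]], beta1 = u[lay$beta[2]])
}

# Log absolute Jacobian determinant of the unconstraining transform,
# evaluated at a constrained state: the C++ log posterior equals
# log_prior(state) + joint_loglik(...) + .log_jacobian(state).
.log_jacobian <- function(state) {
  d <- state$dynamics
  sum(log(state$t) + log1p(-state$t)) +
    sum(log(state$pi)) * (length(state$pi) > 1) +
    sum(log(d$delta)) + sum(log(d$eta)) + sum(log(d$zeta)) +
    sum(log(d$t0_switch) + log1p(-d$t0_switch)) +
    sum(log(d$t0_pulse) + log1p(-d$t0_pulse)) +
    sum(log(state$phi))
}

# Draw a full model state from the priors (used for chain initialization
# and by the simulator when dynamics are sampled rather than fixed).
.draw_state_from_priors <- function(N, gene_ids, K, priors) {
  G <- length(gene_ids)
  h <- .expand_priors(priors, gene_ids, K)
  rtnorm <- function(n, m, s) stats::qnorm(stats::runif(n, stats::pnorm(0, m, s), 1), m, s)
  dyn <- data.frame(
    gene = gene_ids,
    delta = rtnorm(G, h$d_m, h$d_s),
    tau = stats::rnorm(G, h$tau_m, h$tau_s),
    t0_switch = stats::rbeta(G, h$t0s_a, h$t0s_b),
    eta = rtnorm(G, h$e_m, h$e_s),
    zeta = rtnorm(G, h$z_m, h$z_s),
    t0_pulse = stats::rbeta(G, h$t0p_a, h$t0p_b))
  pi <- as.numeric(stats::rgamma(K, shape = h$alpha, rate = 1))
  if (all(pi == 0)) pi <- rep(1, K)
  model_state(t = stats::runif(N), pi = pi / sum(pi), dynamics = dyn,
              phi = stats::rgamma(G, shape = h$phi_a, rate = h$phi_b),
              beta0 = stats::rnorm(1, h$b_m, h$b_s),
              beta1 = stats::rnorm(1, h$b_m, h$b_s))
}

# Assemble the data list consumed by the C++ model.
.model_data <- function(m, panel, priors, epsilon = 0.01) {
  M <- .marker_matrix(panel, m$gene_ids)
  h <- .expand_priors(priors, m$gene_ids, panel$K)
  c(list(Y = m$values, marker = M, K = panel$K, eps = epsilon), h)
}
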