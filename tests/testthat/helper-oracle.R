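# Brute-force oracle for the marginalized cell likelihood: exhaustive
# enumeration over the latent branch z and every dropout pattern
# gamma in {0,1}^G. Tractable only for tiny G; used to validate the
# analytically marginalized implementation.
enumerate_cell_lik <- function(y, t, state, panel, epsilon = 0.01) {
  G <- length(y)
  K <- panel$K
  M <- mixtraj:::.marker_matrix(panel, state$dynamics$gene)
  total <- 0
  for (k in seq_len(K)) {
    mu <- ifelse(M[, k] == 1L,
                 sigmoid_mean(t, state$dynamics$delta, state$dynamics$tau, state$dynamics$t0_switch),
                 pulse_mean(t, state$dynamics$eta, state$dynamics$zeta, state$dynamics$t0_pulse))
    s2 <- (1 + state$phi) * mu + epsilon
    p <- stats::plogis(state$beta0 + state$beta1 * mu)
    branch_sum <- 0
    for (pattern in 0:(2^G - 1)) {
      gamma <- as.integer(intToBits(pattern)[seq_len(G)])
      term <- 1
      for (j in seq_len(G)) {
        pg <- if (gamma[j] == 1) p[j] else 1 - p[j]
        obs <- if (gamma[j] == 1) as.numeric(y[j] == 0) else stats::dnorm(y[j], mu[j], sqrt(s2[j]))
        term <- term * pg * obs
      }
      branch_sum <- branch_sum + term
    }
    total <- total + state$pi[k] * branch_sum
  }
  as.numeric(log(total))
}

# random tiny model instance for oracle comparisons
random_toy <- function(N = NULL, G = NULL, K = NULL) {
  if (is.null(K)) K <- sample(1:3, 1)
  if (is.null(G)) G <- sample(1:3, 1)
  if (is.null(N)) N <- sample(1:3, 1)
  genes <- sprintf("g%d", seq_len(G))
  # every branch gets at least one marker (genes may mark several branches)
  map <- stats::setNames(vector("list", G), genes)
  for (b in seq_len(K)) {
    g <- ((b - 1) %% G) + 1
    map[[g]] <- c(map[[g]], b)
  }
  for (g in seq_len(G)) if (is.null(map[[g]])) map[[g]] <- sample(seq_len(K), 1)
  panel <- suppressWarnings(marker_panel(sprintf("B%d", seq_len(K)), map))
  dyn <- data.frame(gene = genes,
                    delta = runif(G, 0.1, 1), tau = runif(G, -15, 15),
                    t0_switch = runif(G), eta = runif(G, 0.1, 0.6),
                    zeta = runif(G, 0, 80), t0_pulse = runif(G))
  pi <- as.numeric(rgamma(K, 1) + 0.05)
  state <- model_state(t = runif(N), pi = pi / sum(pi), dynamics = dyn,
                       phi = runif(G, 0, 1), beta0 = runif(1, -2, 2),
                       beta1 = runif(1, -6, 1))
  y <- matrix(abs(rnorm(N * G, 0.4, 0.3)), N, G)
  y[runif(N * G) < 0.3] <- 0
  expr <- expression_matrix(y, sprintf("c%d", seq_len(N)), genes, normalized = TRUE)
  list(expr = expr, state = state, panel = panel)
}

# all permutations of 1..n as rows of a matrix
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# small simulated fit shared across tests (computed once per run)
.fit_cache <- new.env(parent = emptyenv())
recovery_fixture <- function() {
  if (!is.null(.fit_cache$recovery)) return(.fit_cache$recovery)
  panel <- default_panel(2, 4)
  sim <- simulate_trajectory(100, panel, dropout_rate = 0.1, seed = 1)
  fit <- suppressWarnings(fit_trajectory(
    sim$expression, panel,
    config = sampler_config(n_chains = 2, n_iter = 2000, n_warmup = 1000, seed = 1)))
  .fit_cache$recovery <- list(sim = sim, fit = fit, panel = panel)
  .fit_cache$recovery
}
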