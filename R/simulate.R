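#' Deterministic reference dynamics for a marker panel
#'
#' The simulator's default gene dynamics emulate a differentiation process
#' in which each lineage has its own cascade of switch-like markers: within
#' a branch, marker activation times are spread evenly across mid-trajectory
#' (0.2 to 0.7), with amplitude `delta = 0.5` (saturating at 1 on the
#' normalized scale) and steepness `tau = 10`. On the branches a gene does
#' not mark it behaves as a transient pulse (`eta = 0.25`, `zeta = 20`)
#' whose midpoints are spread over 0.3 to 0.7. Genes outside the marker map
#' are transient on every branch.
#'
#' @param panel a [marker_panel()].
#' @param gene_ids genes of the expression matrix (panel genes plus any
#'   non-marker genes); defaults to the panel's marker genes.
#' @return A dynamics data.frame as used by [model_state()].
#' @export
default_dynamics <- function(panel, gene_ids = names(panel$marker_map)) {
  G <- length(gene_ids)
  dyn <- data.frame(gene = gene_ids, delta = 0.5, tau = 10, t0_switch = 0.45,
                    eta = 0.25, zeta = 20,
                    t0_pulse = if (G > 1) seq(0.3, 0.7, length.out = G) else 0.5)
  for (k in seq_len(panel$K)) {
    mk <- names(panel$marker_map)[vapply(panel$marker_map, function(b) k %in% b, logical(1))]
    mk <- intersect(mk, gene_ids)
    tt <- if (length(mk) > 1) seq(0.2, 0.7, length.out = length(mk)) else 0.45
    dyn$t0_switch[match(mk, dyn$gene)] <- tt
  }
  dyn
}

#' Reference generating state for a panel
#'
#' Uniform lineage proportions, [default_dynamics()], dispersion
#' `phi = 0.1`, and dropout slope `beta1 = -5` (higher expression, less
#' dropout); the intercept `beta0` is recalibrated inside
#' [simulate_trajectory()] to hit the requested dropout rate.
#'
#' @param n_cells number of cells (pseudotimes are placeholders, resampled
#'   by the simulator).
#' @inheritParams default_dynamics
#' @export
default_state <- function(n_cells, panel, gene_ids = names(panel$marker_map)) {
  dyn <- default_dynamics(panel, gene_ids)
  model_state(t = rep(0.5, n_cells), pi = rep(1 / panel$K, panel$K),
              dynamics = dyn, phi = rep(0.1, nrow(dyn)), beta0 = 0, beta1 = -5)
}

# bisect the dropout intercept so the expected dropout fraction over the
# realized mean matrix matches the target within 1e-4
.calibrate_beta0 <- function(mu, beta1, rate) {
  f <- function(b0) mean(stats::plogis(b0 + beta1 * mu)) - rate
  lo <- -50; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-10) break
  }
  (lo + hi) / 2
}

#' Simulate a branching differentiation dataset
#'
#' Samples the generative model forward: pseudotimes `t_i ~ Uniform(0,1)`,
#' branch labels `z_i ~ Categorical(pi)`, expression
#' `y_ij ~ N(mu_jk(t_i), (1+phi_j) mu + 0.01)` clipped at zero (clipped
#' entries are biological zeros, not dropout), then technical dropout
#' `gamma_ij ~ Bernoulli(plogis(beta0 + beta1 mu_ij))` zeroing masked
#' entries. The dropout intercept is auto-calibrated by bisection so the
#' expected dropout fraction equals `dropout_rate`.
#'
#' @param n_cells number of cells (>= 1).
#' @param panel a [marker_panel()].
#' @param state optional [model_state()]; defaults to [default_state()].
#' @param priors optional [prior_spec()]: when given (and `state` is not),
#'   gene dynamics are drawn from the priors instead of the deterministic
#'   defaults.
#' @param dropout_rate target dropout fraction in \[0, 1).
#' @param n_extra_genes non-marker genes (transient on every branch) added
#'   to the matrix.
#' @param seed integer seed; identical arguments and seed give an
#'   identical dataset.
#' @return A `mixtraj_sim`: `expression` (normalized-scale
#'   [expression_matrix()]), `true_time`, `true_branch`, `dropout_mask`
#'   (N x G logical), the generating `state`, `panel`, and `seed`.
#' @export
simulate_trajectory <- function(n_cells, panel, state = NULL, priors = NULL,
                                dropout_rate = 0.1, n_extra_genes = 0, seed = 1) {
  stopifnot(inherits(panel, "mixtraj_panel"))
  if (n_cells < 1) stop("`n_cells` must be at least 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("`dropout_rate` must lie in [0, 1)")
  gene_ids <- names(panel$marker_map)
  if (n_extra_genes > 0) gene_ids <- c(gene_ids, sprintf("ns_%d", seq_len(n_extra_genes)))

  set.seed(seed)
  if (is.null(state)) {
    state <- if (is.null(priors)) {
      default_state(n_cells, panel, gene_ids)
    } else {
      .draw_state_from_priors(n_cells, gene_ids, panel$K, priors)
    }
  } else {
    if (nrow(state$dynamics) != length(gene_ids))
      stop("`state` dynamics do not cover the panel's genes")
    if (length(state$pi) != panel$K) stop("`state$pi` does not match panel K")
  }
  G <- length(gene_ids)
  M <- .marker_matrix(panel, gene_ids)

  t <- stats::runif(n_cells)
  z <- sample.int(panel$K, n_cells, replace = TRUE, prob = state$pi)
  mu <- matrix(0, n_cells, G)
  for (k in seq_len(panel$K)) {
    idx <- which(z == k)
    if (!length(idx)) next
    for (j in seq_len(G)) {
      mu[idx, j] <- if (M[j, k] == 1L)
        sigmoid_mean(t[idx], state$dynamics$delta[j], state$dynamics$tau[j], state$dynamics$t0_switch[j])
      else
        pulse_mean(t[idx], state$dynamics$eta[j], state$dynamics$zeta[j], state$dynamics$t0_pulse[j])
    }
  }
  s2 <- sweep(mu, 2, 1 + state$phi, "*") + 0.01
  y <- matrix(stats::rnorm(n_cells * G, mu, sqrt(s2)), n_cells, G)
  y[y < 0] <- 0

  if (dropout_rate > 0) {
    beta0 <- .calibrate_beta0(mu, state$beta1, dropout_rate)
    p <- stats::plogis(beta0 + state$beta1 * mu)
    mask <- matrix(stats::runif(n_cells * G) < p, n_cells, G)
    y[mask] <- 0
  } else {
    beta0 <- -50  # dropout switched off; kept finite so the state stays evaluable
    mask <- matrix(FALSE, n_cells, G)
  }
  state$t <- t
  state$beta0 <- beta0

  expr <- expression_matrix(y, cell_ids = sprintf("cell_%03d", seq_len(n_cells)),
                            gene_ids = gene_ids, normalized = TRUE)
  dimnames(mask) <- dimnames(expr$values)
  structure(list(expression = expr, true_time = t, true_branch = z,
                 dropout_mask = mask, state = state, panel = panel, seed = seed),
            class = "mixtraj_sim")
}

#' @export
print.mixtraj_sim <- function(x, ...) {
  cat(sprintf("<mixtraj_sim> %d cells x %d genes, K=%d, %.1f%% dropout (seed %d)\n",
              nrow(x$expression$values), ncol(x$expression$values), x$panel$K,
              100 * mean(x$dropout_mask), x$seed))
  invisible(x)
}
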