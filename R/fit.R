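#' Sampler configuration
#'
#' Defaults follow the reference sampling protocol: four independent chains
#' of 6000 iterations each, the first 3000 as warm-up, initialized from the
#' prior distributions.
#'
#' @param n_chains number of chains (>= 1).
#' @param n_iter iterations per chain, including warm-up.
#' @param n_warmup warm-up iterations per chain (`< n_iter`).
#' @param seed integer seed controlling initialization and sampling.
#' @param target_accept dual-averaging acceptance target.
#' @param max_treedepth No-U-Turn doubling cap.
#' @param init `"prior"` or a [model_state()] used for every chain.
#' @export
sampler_config <- function(n_chains = 4, n_iter = 6000, n_warmup = 3000,
                           seed = 1, target_accept = 0.8, max_treedepth = 10,
                           init = "prior") {
  if (n_chains < 1) stop("`n_chains` must be at least 1")
  if (n_warmup >= n_iter) stop("`n_warmup` must be smaller than `n_iter`")
  if (n_warmup < 1) stop("`n_warmup` must be positive")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_warmup = as.integer(n_warmup), seed = as.integer(seed),
                 target_accept = target_accept,
                 max_treedepth = as.integer(max_treedepth), init = init),
            class = "mixtraj_config")
}

.draw_names <- function(cell_ids, gene_ids, K, branch_names) {
  c(sprintf("t[%s]", cell_ids),
    if (K > 1) sprintf("pi[%s]", branch_names[-K]) else character(0),
    as.vector(t(outer(gene_ids, c("delta", "tau", "t0_switch", "eta", "zeta", "t0_pulse"),
                      function(g, p) sprintf("%s[%s]", p, g)))),
    sprintf("phi[%s]", gene_ids), "beta0", "beta1")
}

# constrain a draws-by-P matrix of unconstrained draws, column-wise
.constrain_draws <- function(U, N, G, K) {
  lay <- .param_layout(N, G, K)
  V <- U
  V[, lay$t] <- stats::plogis(U[, lay$t, drop = FALSE])
  if (K > 1) {
    E <- cbind(exp(U[, lay$pi, drop = FALSE]), 1)
    V[, lay$pi] <- (E / rowSums(E))[, -K, drop = FALSE]
  }
  for (j in seq_len(G)) {
    idx <- lay$dyn(j)
    V[, idx[c(1, 4, 5)]] <- exp(U[, idx[c(1, 4, 5)], drop = FALSE])
    V[, idx[c(3, 6)]] <- stats::plogis(U[, idx[c(3, 6)], drop = FALSE])
  }
  V[, lay$phi] <- exp(U[, lay$phi, drop = FALSE])
  V
}

#' Fit the mixture trajectory model
#'
#' Samples the joint posterior of pseudotimes, lineage proportions, gene
#' dynamic parameters, dispersion, and dropout coefficients by dynamic
#' Hamiltonian Monte Carlo (No-U-Turn), with branch assignments and dropout
#' indicators marginalized analytically. Convergence is declared when every
#' parameter has split R-hat below 1.05 and bulk effective sample size above
#' 200 and fewer than 10% of post-warmup transitions diverged; otherwise the
#' result is returned with `converged = FALSE` and a warning.
#'
#' @param m a normalized `mixtraj_expr`.
#' @param panel a [marker_panel()]; its marker genes must appear in `m`.
#' @param priors a [prior_spec()].
#' @param config a [sampler_config()].
#' @return A `mixtraj_fit` with pooled post-warmup `draws` (constrained
#'   scale, named columns), `chain_id`, per-parameter `rhat` and `ess`,
#'   `branch_prob` (N x K posterior branch probabilities), `point`
#'   (posterior-mode [model_state()]), and `converged`.
#' @export
fit_trajectory <- function(m, panel, priors = prior_spec(),
                           config = sampler_config()) {
  stopifnot(inherits(m, "mixtraj_expr"), inherits(panel, "mixtraj_panel"),
            inherits(config, "mixtraj_config"))
  if (!m$normalized) stop("`m` must be normalized (model scale); run normalize_expression()")
  N <- nrow(m$values); G <- ncol(m$values); K <- panel$K
  data <- .model_data(m, panel, priors)
  if (K > 1) {
    sets <- lapply(seq_len(K), function(k)
      sort(names(panel$marker_map)[vapply(panel$marker_map, function(b) k %in% b, logical(1))]))
    if (all(vapply(sets[-1], identical, logical(1), sets[[1]])))
      warning("all branches share an identical marker set: the mixture is unidentified up to label permutation")
  }

  old_seed <- NULL
  set.seed(config$seed)
  inits <- lapply(seq_len(config$n_chains), function(c) {
    if (identical(config$init, "prior")) {
      .state_to_u(.draw_state_from_priors(N, m$gene_ids, K, priors))
    } else {
      .state_to_u(config$init)
    }
  })
  chains <- cpp_mix_sample(data, inits, config$n_iter, config$n_warmup,
                           config$target_accept, config$max_treedepth)

  n_keep <- config$n_iter - config$n_warmup
  U <- do.call(rbind, lapply(chains, function(ch) ch$draws))
  chain_id <- rep(seq_along(chains), each = n_keep)
  draws <- .constrain_draws(U, N, G, K)
  colnames(draws) <- .draw_names(m$cell_ids, m$gene_ids, K, panel$branch_names)
  lp <- unlist(lapply(chains, function(ch) ch$lp))
  n_div <- sum(vapply(chains, function(ch) ch$n_divergent, numeric(1)))
  div_frac <- n_div / nrow(draws)

  diag <- mcmc_diagnostics(draws, chain_id)
  converged <- diag$converged && div_frac <= 0.10
  if (div_frac > 0.10)
    warning(sprintf("%.1f%% of post-warmup transitions diverged; results are unreliable", 100 * div_frac))
  if (!diag$converged)
    warning("sampler did not converge (split R-hat >= 1.05 or bulk ESS <= 200 for some parameter)")

  bp <- cpp_mix_responsibilities(data, U)
  bp <- bp / rowSums(bp)
  dimnames(bp) <- list(m$cell_ids, panel$branch_names)

  point_vec <- apply(draws, 2, half_sample_mode)
  lay <- .param_layout(N, G, K)
  pi_pt <- if (K > 1) {
    p <- point_vec[lay$pi]
    p <- c(p, max(1 - sum(p), 1e-12))
    p / sum(p)
  } else 1
  dyn_pt <- do.call(rbind, lapply(seq_len(G), function(j) {
    v <- point_vec[lay$dyn(j)]
    data.frame(gene = m$gene_ids[j], delta = v[1], tau = v[2], t0_switch = v[3],
               eta = v[4], zeta = v[5], t0_pulse = v[6])
  }))
  point <- model_state(t = pmin(pmax(point_vec[lay$t], 0), 1), pi = pi_pt,
                       dynamics = dyn_pt, phi = point_vec[lay$phi],
                       beta0 = point_vec[lay$beta[1]], beta1 = point_vec[lay$beta[2]])

  structure(list(draws = draws, chain_id = chain_id, lp = lp,
                 rhat = diag$rhat, ess = diag$ess,
                 n_divergent = n_div, divergent_fraction = div_frac,
                 converged = converged, point = point, branch_prob = bp,
                 panel = panel, cell_ids = m$cell_ids, gene_ids = m$gene_ids,
                 config = config,
                 stepsize = vapply(chains, function(ch) ch$stepsize, numeric(1)),
                 accept = vapply(chains, function(ch) ch$accept, numeric(1))),
            class = "mixtraj_fit")
}

#' @export
print.mixtraj_fit <- function(x, ...) {
  cat(sprintf("<mixtraj_fit> %d cells, %d genes, K=%d; %d chains x %d draws\n",
              length(x$cell_ids), length(x$gene_ids), x$panel$K,
              length(unique(x$chain_id)), sum(x$chain_id == x$chain_id[1])))
  cat(sprintf("  converged: %s (max R-hat %.3f, min ESS %.0f, %.1f%% divergent)\n",
              x$converged, max(x$rhat, na.rm = TRUE), min(x$ess, na.rm = TRUE),
              100 * x$divergent_fraction))
  invisible(x)
}

#' Posterior branch-assignment probabilities
#'
#' For each retained draw the responsibility of branch k for cell i is
#' `pi_k p_k(y_i | .) / sum_k' pi_k' p_k'(y_i | .)`; per-draw responsibilities
#' are averaged over all pooled draws and renormalized, giving an N x K
#' matrix whose rows sum to one.
#'
#' @param fit a `mixtraj_fit`.
#' @return N x K probability matrix.
#' @export
branch_probabilities <- function(fit) {
  stopifnot(inherits(fit, "mixtraj_fit"))
  fit$branch_prob
}

#' Single-draw branch responsibilities from component likelihoods
#'
#' Bayes rule on one parameter draw: given per-branch likelihoods `lik`
#' (or a row per cell) and lineage proportions `pi`, returns the normalized
#' posterior assignment probabilities.
#'
#' @param lik length-K likelihood vector or N x K matrix.
#' @param pi length-K lineage proportions.
#' @export
branch_responsibility <- function(lik, pi) {
  if (is.matrix(lik)) {
    w <- sweep(lik, 2, pi, "*")
    return(w / rowSums(w))
  }
  w <- lik * pi
  w / sum(w)
}

#' Classify cells into terminal branches or progenitors
#'
#' A cell is assigned to its highest-probability branch when that
#' probability reaches `threshold`, and labelled a progenitor otherwise.
#' Ties break deterministically toward the lowest branch index. The
#' threshold must exceed 1/K, or every cell would trivially be assigned.
#'
#' @param branch_prob N x K matrix of branch probabilities (rows on the
#'   simplex), e.g. from [branch_probabilities()].
#' @param threshold assignment threshold in (1/K, 1\].
#' @param branch_names optional branch names; defaults to the matrix
#'   column names.
#' @return A data.frame with `cell_id`, `branch_index` (0 for progenitor),
#'   `branch` (name or `"progenitor"`), and `p_max`.
#' @export
classify_cells <- function(branch_prob, threshold = 0.7, branch_names = colnames(branch_prob)) {
  if (inherits(branch_prob, "mixtraj_fit")) branch_prob <- branch_prob$branch_prob
  K <- ncol(branch_prob)
  if (threshold <= 1 / K || threshold > 1)
    stop(sprintf("`threshold` must lie in (1/K, 1] = (%.3f, 1]", 1 / K))
  if (is.null(branch_names)) branch_names <- sprintf("branch%d", seq_len(K))
  p_max <- apply(branch_prob, 1, max)
  k_star <- apply(branch_prob, 1, which.max)  # which.max takes the lowest index on ties
  idx <- ifelse(p_max >= threshold, k_star, 0L)
  data.frame(cell_id = if (is.null(rownames(branch_prob))) sprintf("cell_%d", seq_len(nrow(branch_prob))) else rownames(branch_prob),
             branch_index = as.integer(idx),
             branch = ifelse(idx == 0L, "progenitor", branch_names[pmax(idx, 1L)]),
             p_max = p_max,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior pseudotime point estimates
#'
#' Half-sample-mode summaries of the pooled pseudotime draws.
#'
#' @param fit a `mixtraj_fit`.
#' @return Named numeric vector of length N.
#' @export
pseudotime <- function(fit) {
  stopifnot(inherits(fit, "mixtraj_fit"))
  stats::setNames(fit$point$t, fit$cell_ids)
}

#' Half-sample mode
#'
#' Robust mode estimator for continuous draws: recursively keeps the
#' shortest interval containing half the remaining sorted values.
#'
#' @param x numeric vector.
#' @export
half_sample_mode <- function(x) {
  x <- sort(x[is.finite(x)])
  while (length(x) > 3) {
    n <- length(x)
    h <- ceiling(n / 2)
    widths <- x[h:n] - x[seq_len(n - h + 1)]
    i <- which.min(widths)
    x <- x[i:(i + h - 1)]
  }
  if (length(x) == 0) return(NA_real_)
  if (length(x) <= 2) return(mean(x))
  if (x[2] - x[1] < x[3] - x[2]) mean(x[1:2])
  else if (x[3] - x[2] < x[2] - x[1]) mean(x[2:3])
  else x[2]
}
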