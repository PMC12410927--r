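# MCMC convergence diagnostics: split R-hat and bulk effective sample size,
# computed per scalar parameter across chains (Gelman et al. formulas with
# Geyer's initial monotone sequence for the autocorrelation sum).

.split_halves <- function(chains) {
  out <- list()
  for (ch in chains) {
    n <- length(ch)
    h <- floor(n / 2)
    out <- c(out, list(ch[seq_len(h)], ch[(n - h + 1):n]))
  }
  out
}

# autocovariance by FFT, biased (divided by n), as used by ESS estimators
.autocov <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / m
  ac[seq_len(n)] / n
}

#' Split R-hat for one parameter
#'
#' Potential scale reduction computed after splitting each chain in half,
#' so within-chain trends register as apparent non-convergence.
#'
#' @param chains list of numeric vectors (one per chain) or a matrix with
#'   one column per chain.
#' @return Scalar R-hat (1 for a zero-variance parameter).
#' @export
split_rhat <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  sp <- .split_halves(chains)
  n <- min(lengths(sp))
  sp <- lapply(sp, function(x) x[seq_len(n)])
  mns <- vapply(sp, mean, numeric(1))
  vars <- vapply(sp, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(mns)
  if (!is.finite(W) || W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bulk effective sample size
#'
#' Combined multi-chain ESS: per-chain autocovariances are averaged,
#' converted to the cross-chain autocorrelation via the between-chain
#' variance, and summed with Geyer's initial positive/monotone truncation.
#' Chains are split in half first, matching [split_rhat()].
#'
#' @param chains list of numeric vectors (one per chain) or a matrix with
#'   one column per chain.
#' @return Scalar ESS estimate.
#' @export
ess_bulk <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  sp <- .split_halves(chains)
  n <- min(lengths(sp))
  if (n < 4) return(NA_real_)
  sp <- lapply(sp, function(x) x[seq_len(n)])
  m <- length(sp)
  mns <- vapply(sp, mean, numeric(1))
  vars <- vapply(sp, stats::var, numeric(1))
  W <- mean(vars)
  B_over_n <- if (m > 1) stats::var(mns) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  if (!is.finite(var_plus) || var_plus == 0) return(m * n)
  # cross-chain autocorrelation: rho_t = 1 - (W - c_t) / var_plus,
  # with c_t the chain-averaged unbiased autocovariance (c_0 = W, rho_0 = 1)
  acov <- rowMeans(vapply(sp, .autocov, numeric(n))) * n / (n - 1)
  rho <- 1 - (W - acov) / var_plus
  # Geyer initial positive, monotone-decreasing pair sums
  tau <- -1
  prev <- Inf
  k <- 0
  while (2 * k + 2 <= n) {
    p <- rho[2 * k + 1] + rho[2 * k + 2]
    if (!is.finite(p) || p <= 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + 2 * p
    k <- k + 1
  }
  ess <- m * n / max(tau, 1 / (m * n))
  min(ess, m * n * log10(max(m * n, 10)))
}

#' Convergence diagnostics for a set of draws
#'
#' @param draws pooled draws matrix (rows = iterations, columns =
#'   parameters) or a `mixtraj_fit`.
#' @param chain_id integer vector assigning each row to a chain.
#' @return List with per-parameter `rhat` and `ess` plus the overall
#'   `converged` flag: `TRUE` iff every R-hat < 1.05 and every ESS > 200.
#'   With a single chain R-hat cannot be computed: it is reported as `NA`
#'   and `converged` is `FALSE`.
#' @export
mcmc_diagnostics <- function(draws, chain_id = NULL) {
  if (inherits(draws, "mixtraj_fit")) {
    chain_id <- draws$chain_id
    draws <- draws$draws
  }
  if (is.null(chain_id)) chain_id <- rep(1L, nrow(draws))
  ids <- unique(chain_id)
  single <- length(ids) < 2
  cols <- seq_len(ncol(draws))
  rhat <- numeric(length(cols))
  ess <- numeric(length(cols))
  for (j in cols) {
    chains <- lapply(ids, function(c) draws[chain_id == c, j])
    sds <- vapply(chains, stats::sd, numeric(1))
    if (all(sds == 0)) { # pinned parameter carries no sampling error
      rhat[j] <- 1
      ess[j] <- nrow(draws)
      next
    }
    rhat[j] <- if (single) NA_real_ else split_rhat(chains)
    ess[j] <- ess_bulk(chains)
  }
  names(rhat) <- names(ess) <- colnames(draws)
  converged <- !single && all(rhat < 1.05, na.rm = FALSE) && all(ess > 200, na.rm = FALSE)
  list(rhat = rhat, ess = ess, converged = isTRUE(converged))
}
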