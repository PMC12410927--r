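#' Prior specification for the mixture model
#'
#' Hyperparameters of the hierarchical priors, all overridable globally or
#' per gene. Defaults are chosen for the \[0,1\]-normalized observation
#' scale:
#' \describe{
#'   \item{delta, eta}{amplitude / pulse peak: Normal(0.5, 0.5^2) truncated
#'     to be non-negative, so a marker's saturating level 2*delta sits near
#'     the top of the normalized range.}
#'   \item{tau}{switch steepness: Normal(10, 5^2). The positive centre
#'     anchors the direction of pseudotime (markers activate along the
#'     branches they mark); the model is otherwise exactly invariant under
#'     time reversal. Set a negative mean per gene for markers that switch
#'     off.}
#'   \item{zeta}{pulse width: Normal(50, 25^2) truncated non-negative.}
#'   \item{t0_switch, t0_pulse}{activation time / pulse midpoint:
#'     Beta(2, 2), mildly favouring mid-trajectory events.}
#'   \item{phi}{gene-wise dispersion: Gamma(shape 2, rate 4).}
#'   \item{beta}{dropout intercept and slope: Normal(0, 0.01) read as
#'     variance 0.01 (sd 0.1).}
#'   \item{dirichlet_alpha}{lineage proportion concentration; `NULL` means
#'     the symmetric 1/K.}
#' }
#'
#' @param delta,tau,eta,zeta,beta length-2 numeric `(mean, sd)`.
#' @param t0_switch,t0_pulse length-2 numeric Beta `(a, b)`.
#' @param phi length-2 numeric Gamma `(shape, rate)`.
#' @param dirichlet_alpha positive scalar or `NULL` for 1/K.
#' @param genes optional named list of per-gene overrides, each a list with
#'   any of the gene-level entries above, e.g.
#'   `list(Gata6 = list(tau = c(-10, 5)))`.
#' @return An object of class `mixtraj_priors`.
#' @export
prior_spec <- function(delta = c(0.5, 0.5), tau = c(10, 5),
                       eta = c(0.5, 0.5), zeta = c(50, 25),
                       t0_switch = c(2, 2), t0_pulse = c(2, 2),
                       phi = c(2, 4), beta = c(0, 0.1),
                       dirichlet_alpha = NULL, genes = list()) {
  chk2 <- function(x, nm, positive = c(2)) {
    if (length(x) != 2 || !is.numeric(x)) stop(sprintf("`%s` must be length-2 numeric", nm))
    if (any(x[positive] <= 0)) stop(sprintf("`%s` hyperparameters must be strictly positive", nm))
    as.numeric(x)
  }
  p <- list(delta = chk2(delta, "delta"), tau = chk2(tau, "tau"),
            eta = chk2(eta, "eta"), zeta = chk2(zeta, "zeta"),
            t0_switch = chk2(t0_switch, "t0_switch", c(1, 2)),
            t0_pulse = chk2(t0_pulse, "t0_pulse", c(1, 2)),
            phi = chk2(phi, "phi", c(1, 2)), beta = chk2(beta, "beta"),
            dirichlet_alpha = dirichlet_alpha, genes = genes)
  if (!is.null(dirichlet_alpha) && dirichlet_alpha <= 0)
    stop("`dirichlet_alpha` must be strictly positive")
  structure(p, class = "mixtraj_priors")
}

#' Read a prior specification from YAML or JSON
#'
#' Top-level keys mirror the arguments of [prior_spec()]; a `genes` mapping
#' holds per-gene overrides.
#'
#' @param path YAML or JSON file.
#' @return A [prior_spec()].
#' @export
read_prior_spec <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read priors file '%s': no such file", path))
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- spec[intersect(names(spec), setdiff(names(formals(prior_spec)), "genes"))]
  args <- lapply(args, unlist)
  if (!is.null(spec$genes))
    args$genes <- lapply(spec$genes, function(g) lapply(g, unlist))
  do.call(prior_spec, args)
}

# Expand a prior_spec into per-gene hyperparameter vectors aligned with
# gene_ids, for the sampler's data list and for log_prior().
.expand_priors <- function(priors, gene_ids, K) {
  stopifnot(inherits(priors, "mixtraj_priors"))
  G <- length(gene_ids)
  take <- function(field, slot) {
    v <- rep(priors[[field]][slot], G)
    for (g in names(priors$genes)) {
      ov <- priors$genes[[g]][[field]]
      if (!is.null(ov)) {
        j <- match(g, gene_ids)
        if (!is.na(j)) v[j] <- ov[slot]
      }
    }
    v
  }
  alpha <- if (is.null(priors$dirichlet_alpha)) 1 / K else priors$dirichlet_alpha
  list(
    d_m = take("delta", 1), d_s = take("delta", 2),
    tau_m = take("tau", 1), tau_s = take("tau", 2),
    e_m = take("eta", 1), e_s = take("eta", 2),
    z_m = take("zeta", 1), z_s = take("zeta", 2),
    t0s_a = take("t0_switch", 1), t0s_b = take("t0_switch", 2),
    t0p_a = take("t0_pulse", 1), t0p_b = take("t0_pulse", 2),
    phi_a = take("phi", 1), phi_b = take("phi", 2),
    b_m = priors$beta[1], b_s = priors$beta[2],
    alpha = alpha)
}
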