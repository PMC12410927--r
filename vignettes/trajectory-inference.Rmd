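---
title: "Model and methods: semi-supervised mixture trajectory inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: semi-supervised mixture trajectory inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell RNA-seq snapshots carry no time axis. Trajectory inference
reconstructs one: a latent *pseudotime* per cell and, for branching
differentiation, an assignment of each cell to one of K terminal lineages.
Fully unsupervised methods infer both from global transcriptome similarity
and are sensitive to noise, sparsity, and tuning. `mixtraj` instead takes
the branching topology and a small curated marker panel as *prior
knowledge*, and fits a generative model of just those markers. This buys
robustness at the cost of requiring domain knowledge: the topology is an
input, never discovered.

## The generative model

For cell $i$ with expression vector $y_i$ over $G$ marker genes, we posit a
latent pseudotime $t_i \sim \mathrm{Uniform}(0,1)$ and a latent lineage
$z_i \sim \mathrm{Categorical}(\pi)$ with
$\pi \sim \mathrm{Dirichlet}(1/K,\dots,1/K)$.

Conditional on $z_i = k$, gene $j$ has a time-dependent mean:

* **switch-like** (gene marks lineage $k$):
  $\mu_{ij} = 2\delta_j \,/\, (1 + e^{-\tau_j (t_i - t^{(0)}_j)})$ — a
  logistic activation with amplitude $\delta_j$ (the curve saturates at
  $2\delta_j$), steepness $\tau_j$, activation time $t^{(0)}_j$;
* **transient** (gene does not mark lineage $k$):
  $\mu_{ij} = 2\eta_j \, e^{-\zeta_j (t_i - t^{(0)}_j)^2}$ — a Gaussian
  pulse peaking at $2\eta_j$ with width parameter $\zeta_j$.

The same gene therefore behaves differently under different branches; the
panel decides which role applies where. A gene may mark several branches;
genes in the matrix but absent from the panel are transient everywhere.

Observation noise is Gaussian with mean-dependent variance
$\Sigma_{ij} = (1+\phi_j)\,\mu_{ij} + \epsilon$, $\epsilon = 0.01$, and the
per-gene dispersion $\phi_j \sim \mathrm{Gamma}(2, 4)$. Technical dropout
enters through a latent indicator
$\gamma_{ij} \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_0 + \beta_1
\mu_{ij}))$; when $\gamma_{ij}=1$ the observation is an exact zero. With
$\gamma$ marginalized, an observed zero contributes
$p_{ij} + (1-p_{ij})\,N(0;\mu_{ij},\Sigma_{ij})$ — the point mass plus the
continuous density evaluated at zero, the standard zero-inflation
convention — and a nonzero value contributes
$(1-p_{ij})\,N(y_{ij};\mu_{ij},\Sigma_{ij})$. The cell likelihood
marginalizes the lineage:
$p(y_i \mid t_i, \pi, \Theta) = \sum_k \pi_k \prod_j p_k(y_{ij}\mid\cdot)$,
evaluated with log-sum-exp throughout.

"Multivariate normal" here means independent per-gene normals (diagonal
covariance), as the per-gene mean/variance formulas imply; correlated gene
noise is out of scope.

## Priors, defaults, and identifiability

All defaults target the model's observation scale: gene-wise min–max
normalized $\log(1+x)$ expression in $[0,1]$. `log1p` is used so exact
zeros stay exactly zero and remain candidate dropout events (the base of
the log is a convention; it only rescales the pre-normalization axis).

| parameter | prior | default | why |
|---|---|---|---|
| $\delta_j, \eta_j$ | Normal, truncated $\ge 0$ | $N(0.5, 0.5^2)$ | saturating level $2\delta$ spans the normalized range |
| $\tau_j$ | Normal | $N(10, 5^2)$ | see below |
| $\zeta_j$ | Normal, truncated $\ge 0$ | $N(50, 25^2)$ | pulses narrower than the trajectory |
| $t^{(0)}_j$ (both roles) | Beta | $\mathrm{Beta}(2,2)$ | mild preference for mid-trajectory events |
| $\phi_j$ | Gamma(shape, rate) | $(2, 4)$ | weak, mean 0.5 |
| $\beta_0,\beta_1$ | Normal | $N(0, 0.01)$ (variance) | tight regularization of the dropout link |

The switch steepness prior is centred at $+10$, not 0, and this is a
deliberate identifiability anchor: the likelihood is *exactly* invariant
under time reversal ($t \to 1-t$, $\tau \to -\tau$, $t^{(0)} \to
1-t^{(0)}$), and the non-negativity of $\delta$ does not break that
symmetry. A symmetric steepness prior therefore leaves two mirror-image
posterior modes and independent chains land in either one, which is both a
convergence failure and a scientific ambiguity. Centring $\tau$ on a
positive value encodes the reading that markers *activate* along the
lineages they mark, which fixes the direction of pseudotime. A marker known
to switch off can be given a negative prior mean per gene in the priors
file. No post-hoc flipping of the reported pseudotime is ever performed.

The $t^{(0)}$ symbol is reused by switch and pulse roles in the field's
notation; internally they are separate parameters (`t0_switch`,
`t0_pulse`). Dispersion is one $\phi_j$ per gene, shared across branches.

## Posterior computation

The posterior $p(T, \pi, \Theta \mid Y) \propto p(Y \mid T,\pi,\Theta)\,
p(T)\,p(\pi)\,p(\Theta)$ is sampled with a dynamic Hamiltonian Monte Carlo
sampler (multinomial No-U-Turn variant with dual-averaging step size,
target acceptance 0.8, and diagonal mass-matrix adaptation in doubling
windows), written for this package behind a log-density-plus-gradient
interface. All parameters are transformed to unconstrained scales (logit
for times, log for non-negative scalars, additive-log-ratio for $\pi$) with
the appropriate Jacobians; the discrete latents $z$ and $\gamma$ are
marginalized analytically, which gradient-based MCMC requires. Defaults
follow the standard protocol of four chains of 6000 iterations (3000
warm-up), initialized from the priors.

Two parameter groups have genuinely multimodal 1-D conditionals that
leapfrog trajectories cannot cross: the per-cell pseudotimes (a cell with
ambiguous expression may fit several time wells) and the per-gene
activation/midpoint times. Each HMC transition is therefore followed by an
exact Metropolis-corrected conditional update of every such coordinate,
proposing from a piecewise-constant approximation of its conditional on a
201-point grid. Both kernels leave the posterior invariant, so their
composition does too; the sweep is what lets two short chains agree on
which well each cell occupies.

Convergence is declared when every scalar parameter has split $\hat R <
1.05$ and bulk effective sample size $> 200$, and fewer than 10% of
post-warmup transitions diverged; otherwise the fit carries
`converged = FALSE` and a warning — never a silent pass. $\hat R$ and ESS
are computed in-package (split-half $\hat R$; chain-averaged
autocovariance with Geyer's initial monotone truncation for ESS).

Point summaries use the half-sample mode on pooled draws, the package's
reading of "posterior mode" for continuous scalars. Branch-assignment
probabilities are computed per draw by Bayes' rule,
$p(z_i = k \mid \cdot) \propto \pi_k p_k(y_i \mid \cdot)$, then averaged
over draws and renormalized — a mode of simplex-valued draws is
ill-defined, so the posterior mean is used for this one summary. A cell is
assigned to its top branch when that probability reaches the user threshold
`threshold = 0.7` (exposed as `--assign-threshold`), and is otherwise a
*progenitor*; the threshold must exceed $1/K$. Ties break toward the lowest
branch index, deterministically.

## The simulator as study design

`simulate_trajectory()` samples the generative process forward and is the
package's test bed. Its defaults are fixed study conditions, not tuning
knobs: uniform lineage proportions; per-branch marker cascades with
$\delta = 0.5$, $\tau = 10$ and activation times spread evenly over
$[0.2, 0.7]$; off-branch pulses with $\eta = 0.25$, $\zeta = 20$ and
midpoints over $[0.3, 0.7]$; dispersion $\phi = 0.1$; dropout slope
$\beta_1 = -5$ with the intercept bisected so the realized dropout fraction
matches the requested rate (the sweep axis spans 10–60%). Negative
Gaussian draws are clipped to zero and *not* recorded as dropout, keeping
the observation space consistent with normalized data. Ground-truth times,
branch labels, the dropout mask, and the full generating state are
returned.

What the simulator does and does not emulate: it produces switch-like
marker activation, transient off-branch pulses, mean-dependent
overdispersion, and calibrated dropout — the features the model is built
around — but not UMI-level count noise, gene–gene regulatory correlation,
or batch structure. Passing recovery tests on these data shows the
implementation inverts its own generative process; it does not by itself
certify performance on real tissues.

One property of the model matters for interpreting any recovery study: the
variance law $\Sigma = (1+\phi)\mu + \epsilon$ on a $[0,1]$ mean scale
implies a signal-to-noise ratio below one over most of the dynamic range.
Data sampled faithfully from the model are therefore intrinsically noisy,
and even the Bayes-optimal decoder *given the true parameters* plateaus
near Spearman $\approx 0.85$ and per-branch F1 $\approx 0.83$ at threshold
0.7 for 100 cells, two branches, and four markers per branch (computable
exactly by 1-D quadrature over $t$). Fits should be judged against that
ceiling, not against 1.0.

## Downstream analyses

**Differentiation potential.** The Shannon entropy of a cell's branch
probabilities, $DP_i = -\sum_k p_{ik} \log p_{ik}$, in nats by default
(base 2 via a flag); $0\log 0 = 0$. Committed cells score 0, maximally
uncertain cells $\log K$. Across states it is compared with a global
Kruskal–Wallis test and one-tailed Mann–Whitney U tests for ordered state
pairs (earlier state expected higher); with exactly two groups MWU is the
two-group special case of KW. Exact U distributions are used for groups of
at most 20 without ties, the tie-corrected normal approximation otherwise.

**Branch-specific genes.** For the cells assigned to one branch, each gene
is scored by a Bayes factor between M0 ($y \sim N(\mu, \sigma^2)$,
constant) and M1 ($y \sim N(2\delta/(1+e^{-\tau(t-t^{(0)})}), \sigma^2)$,
sigmoidal in the inferred pseudotime). Marginal likelihoods are estimated
by iterative bridge sampling over HMC draws with a moment-matched Gaussian
proposal (half the draws fit the proposal, half enter the bridge); the
harmonic-mean estimator is avoided as unstable, and a Laplace approximation
is the flagged fallback when the bridge iteration fails. Evidence follows
the printed three-way rule: $BF_{10} > 10$ strong, $1 < BF_{10} \le 10$
moderate, $\le 1$ null. Since the test conditions on pseudotime, the M1
steepness prior here is symmetric ($N(0, 10^2)$); $\sigma$ gets a
half-normal(0.5) scale prior. Progenitor cells are excluded by default
(they can be included with a flag, since each branch is in truth a mixture
of committed and progenitor cells). Top genes are ranked by Bayes factor
and then ordered by activation time to reconstruct regulator cascades.

## Numerical choices and edge cases

* Constant genes normalize to all-zeros with a warning; they carry no
  information and are effectively ignored by the likelihood's flat curves.
* `normalize_expression()` refuses to run twice; simulated data are born
  on the model scale and flagged as such.
* Duplicate gene ids are an error (markers must be unambiguous); duplicate
  cell ids are suffixed with a warning.
* Variance never falls below $\epsilon = 0.01$; dropout and sigmoid links
  are evaluated with overflow-safe log1p/softplus forms.
* A panel in which all branches share an identical marker set makes the
  mixture unidentified up to label permutation; the fit warns.
* Degenerate pseudotimes (all equal) make M1 unidentifiable; the gene test
  refuses them. Gene tests need at least 10 cells by default.
* Kendall's tau is computed by the pairwise-sign formula over ordered
  pairs with no tie correction (tied pairs vanish from the numerator while
  the denominator keeps $n(n-1)$); the tie-corrected tau-b is reported
  alongside under its own name.
* In per-branch F1, progenitor predictions count as "not this branch" for
  every terminal branch.

## Problem sizes used by the test suite

The suite exercises full fits at 100 cells, 8–12 genes, two to three
branches, with two chains of 2000 iterations (1000 warm-up) — the default
protocol scaled down, chosen as the smallest design at which convergence
diagnostics and recovery are meaningful for this model class. Likelihood
correctness is established separately by exhaustive-enumeration oracles on
tiny instances (up to 3 cells, 3 genes, 3 branches, all $2^G$ dropout
patterns), where exactness to 1e-10 is the bar.

## Known limitations

* Accuracy inherits the quality of the supplied topology and panel; a
  wrong topology biases the fit rather than being detected.
* Dynamics are restricted to one sigmoid and one pulse template per gene
  per role; oscillatory or multimodal kinetics are not representable.
* HMC over a few hundred cells takes minutes; variational or GPU backends
  are out of scope.
* The dropout link shares $\beta_0, \beta_1$ across genes; gene-specific
  capture efficiency is not modelled.
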