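# mixtraj

Semi-supervised Bayesian trajectory inference from single-cell expression
of a small marker-gene panel.

## The problem

Single-cell RNA-seq captures static snapshots of dynamic differentiation
processes. Trajectory inference methods reconstruct a *pseudotime* — each
cell's progress along its developmental path — and, for branching systems,
assign cells to lineages. Most methods do this unsupervised from global
transcriptome similarity, which makes them sensitive to technical noise,
sparsity, and tuning choices. `mixtraj` is for the setting where the
biology is partly known: the user supplies the branching topology (K
terminal lineages) and a curated panel of marker genes, and the package
infers everything else from a generative model of just those markers.

It is aimed at analysts who have a well-characterized system (known
lineages with established markers, typically four or more per lineage) and
want probabilistic, interpretable output: posterior pseudotimes, lineage
proportions, per-cell branch-assignment probabilities, gene activation
times, a per-cell differentiation-potential score, and Bayes-factor tests
for branch-specific genes.

## The model

Cellular differentiation is a K-component mixture over latent lineages.
For cell *i* with pseudotime *t<sub>i</sub>* ∈ [0,1] and lineage
*z<sub>i</sub>* = *k*, gene *j*'s mean expression is

* **switch-like** where gene *j* marks lineage *k*:
  μ = 2δ<sub>j</sub> / (1 + exp(−τ<sub>j</sub>(t − t<sub>j</sub><sup>(0)</sup>)))
* **transient** elsewhere:
  μ = 2η<sub>j</sub> · exp(−ζ<sub>j</sub>(t − t<sub>j</sub><sup>(0)</sup>)²)

with variance Σ = (1+φ<sub>j</sub>)μ + 0.01 and zero inflation through a
dropout indicator with probability logit⁻¹(β₀ + β₁μ). The hierarchical
priors are t<sub>i</sub> ~ Uniform(0,1), π ~ Dirichlet(1/K,…,1/K),
z<sub>i</sub> ~ Categorical(π), plus truncated-normal/Beta/Gamma priors on
the gene-level parameters. The posterior over pseudotimes, proportions,
dynamics, dispersion, and dropout coefficients is sampled by a built-in
No-U-Turn Hamiltonian Monte Carlo sampler (discrete latents marginalized),
interleaved with exact conditional updates for the multimodal time
coordinates. See the methods vignette
(`vignettes/trajectory-inference.Rmd`) for the full account.

## Worked example

Simulate a two-branch differentiation with four markers per branch and 10%
dropout, fit it, and inspect the results (about three minutes on one CPU):

```r
library(mixtraj)

panel <- default_panel(2, markers_per_branch = 4)
sim <- simulate_trajectory(100, panel, dropout_rate = 0.1, seed = 1)
sim
#> <mixtraj_sim> 100 cells x 8 genes, K=2, 10.2% dropout (seed 1)

fit <- fit_trajectory(sim$expression, panel,
                      config = sampler_config(n_chains = 2, n_iter = 2000,
                                              n_warmup = 1000, seed = 1))
fit
#> <mixtraj_fit> 100 cells, 8 genes, K=2; 2 chains x 1000 draws
#>   converged: FALSE (max R-hat 1.010, min ESS 176, 0.0% divergent)

# pseudotime accuracy against the simulator's ground truth
correlations(pseudotime(fit), sim$true_time)$spearman
#> [1] 0.7444344

# branch assignment at the 0.7 probability threshold
cls <- classify_cells(fit$branch_prob, threshold = 0.7)
table(cls$branch)
#>
#>    branch1    branch2 progenitor
#>         57         35          8

# differentiation potential: entropy of branch probabilities, in nats
dp <- differentiation_potential(fit$branch_prob)
cor(dp, sim$true_time, method = "spearman")
#> [1] -0.3524272
```

Two readings of this output matter. First, `converged: FALSE` here is the
convergence contract being strict, not a failed fit: the chains agree
closely (maximum split R-hat 1.010, no divergences), but at this
deliberately short two-chain budget a few pulse-midpoint parameters end
with bulk ESS slightly under the 200 bar. Second, the Spearman correlation of about 0.74 should be read
against this design's information ceiling: data simulated faithfully from
the model's mean-dependent noise law are intrinsically hard, and the
Bayes-optimal decoder *given the true parameters* reaches only about 0.85
here (the methods vignette derives this). The negative DP–time correlation
is the expected signature of commitment: early cells sit near maximum
entropy (log 2 ≈ 0.69 nats), late cells near 0.

Branch-specific genes are detected by Bayes-factor comparison of a
sigmoidal against a constant expression model:

```r
t_obs <- runif(50)
y <- pmax(sigmoid_mean(t_obs, 0.5, 20, 0.5) + rnorm(50, 0, 0.05), 0)
test_branch_gene(y, t_obs, gene_id = "Gata6", branch = "endoderm", seed = 1)
#> <mixtraj_genetest> Gata6 / endoderm: BF10 = 4.74e+43 (strong)
```

A command-line interface wrapping the same functions
(`simulate`, `fit`, `classify`, `test-genes`, `evaluate`) is installed at
`system.file("cli", "mixtraj", package = "mixtraj")`.

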