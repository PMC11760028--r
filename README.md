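# ptraj: process-time trajectory inference from unspliced and spliced counts

Single-cell RNA-seq snapshots capture cells spread along ongoing
dynamical processes. Most trajectory tools order cells by a descriptive
"pseudotime" with no physical units, which makes results hard to
interpret or falsify. ptraj instead fits a generative model in which
every cell has a latent **process time** `t ∈ [0, 1]` — its position
along a defined process, as a fraction of the process length — and a
latent lineage on a user-supplied graph of transcriptional states. The
package is for analysts who have matched unspliced/spliced count
matrices (e.g. from kallisto|bustools or velocyto output) and a
hypothesis about the state structure of their system.

## The model

Per gene, each state `s` has a transcription rate `α_s`; splicing and
degradation rates `β`, `γ` are constant. Along lineage `l` the mean
copy numbers follow the kinetic ODEs

    dλ_u/dt = A_l(t) − β λ_u,      dλ_s/dt = β λ_u − γ λ_s,

where `A_l(t)` is piecewise constant, equal to `α` of the state active
in the current time segment `(τ_{k−1}, τ_k]` (`τ_0 = 0`, `τ_K = 1`),
starting from the steady state of the lineage's initial state. Observed
counts are Poisson, `x_ijc ~ Poisson(r_i λ_jc(l_i, t_i))`, with
cell-wise relative read depth `r_i` estimated from near-Poissonian
genes via the mean normalized covariance between genes. A fixed uniform
sampling prior over `(0, 1]` makes the parameters identifiable, so `β`
and `γ` are real rates per unit process time and DE genes can be called
directly from fold changes in `α` across states.

Inference is EM on a discretized time grid (exact discrete posteriors;
analytic per-gene gradients in the M-step; shared or gene-wise switch
times), with multiple random restarts, and model assessment built in:
a Poisson-mixture cluster baseline, gene selection by relative
gene-wise likelihood, AIC/BIC/held-out ELBO, per-gene Fisher
information, restart average precision and bootstrap stability.

## A worked example

Simulate a bifurcation (two lineages sharing a progenitor state), then
run the standard workflow: read-depth estimation, trajectory fit,
cluster baseline, gene selection.

```r
library(ptraj)
st  <- trajectory_structure("[[0,1,2],[0,1,3]]")   # 0 at t=0, then 1, then 2 or 3
sim <- simulate_trajectory(st, n_cells = 1000, n_genes = 120, seed = 7)

estimate_read_depth(sim$data)
#> Read-depth estimate: xi = 0.2419, 96 Poissonian genes (2 iteration(s))

fit <- fit_trajectory(sim$data, st,
                      traj_config(n_restarts = 10, n_iterations = 100,
                                  grid_M = 100, seed = 8))
fit
#> Process-time trajectory fit (synchronized model)
#>   1000 cells, 120 genes, 2 lineage(s), 2 segment(s), grid M = 100
#>   ELBO -421526.65 after 12 iteration(s), 10 restart(s), converged
#>   switch times: 0.000 0.404 1.000
```

The simulation's true switch time is 0.5; the fitted 0.404 is early
because the shared first segment and the branch states are only weakly
distinguished over 120 genes. The
read-depth CV² estimate 0.242 matches the simulated Beta law
(CV² = 0.25). Comparing to the truth:

```r
m <- evaluation_metrics(sim$truth, fit)
#> time RMSE 0.065, correlation 0.984, lineage accuracy 0.979
```

so the posterior-mean process time of a cell is off by about 6% of the
trajectory length on average. Gene selection against the cluster
baseline keeps only genuinely dynamic genes and ranks them by
transcription-rate fold change:

```r
mix <- fit_poisson_mixture(sim$data, 4, n_restarts = 5, seed = 9)
sel <- select_dynamic_genes(trajectory_gene_likelihood(fit),
                            mixture_gene_likelihood(mix), fit$kinetics)
#> 58 dynamic genes selected; 58 are truly variable
head(rank_de_genes(fit$kinetics, sel), 3)
#>    gene fold_change
#> 2     2    26.06931
#> 14   15    16.36940
#> 53   55    14.87889
```

`summary(fit)` reports AIC/BIC and the restart ELBO spread;
`restart_average_precision(fit)` and `bootstrap_stability(fit)`
quantify how trustworthy the ordering is; `plot(fit)` draws the
posterior heatmap or gene phase portraits; `fit_desynchronized(fit)`
refines the fit with gene-wise switch times. `run_pipeline()` chains
the whole workflow from Matrix Market count files to a JSON report, and
`inst/cli/ptraj.R` exposes the same steps as a command line.

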