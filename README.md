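# hemaclone

Clone-size distributions of lentivirus-marked hematopoiesis: a neutral
three-pool model, its exact steady-state laws, a stochastic simulator, and
maximum-likelihood inference of the effective HSC differentiation rate and
the number of actively contributing stem cells.

## Who this is for

Groups analyzing clonal lineage-tracking data — viral integration sites
(VIS), barcodes, or transposon tags — where each blood sample yields read
counts `q` per detected clone. The package answers: what clone-size
distribution does a neutral, carrying-capacity-regulated hematopoietic
system produce, and what do measured histograms imply about HSC behavior?

## The model in brief

`C` marked and `U` unmarked HSCs each seed progenitors by asymmetric
division at rate `α` (per month). Progenitors replicate at the regulated
rate `r(N_p) = pK/(N_p + K)`, die at `μ_p`, and terminally differentiate at
`ω` (symmetric with probability `η`), giving the combined removal rate
`μ = μ_p + ηω`. Differentiated cells turn over at `μ_d`. Counting clones by
size (the number of lineages with exactly `k` progenitor cells) yields a
birth–death–immigration ladder whose steady state is negative binomial:

    P_k = (1 − r̄)^a · Γ(a + k)/(Γ(a) k!) · r̄^k,   a = α/r,  r̄ = r/μ = 1 − δ

with the log-series head `r̄^k k^{a−1}` for `a < 1`. Sequencing `S` of
`N_d` marked cells (`ε = S/N_d`) thins clone sizes to reads,
`q | k ~ Poisson(εw·k)` with `w = (1 + η)ω/μ_d`, and the resulting
histogram depends on the mechanism essentially only through

    a = α/r   and   R = εw / ln(1/r̄) ≈ εw/δ .

Fitting `(a, R)` to a read histogram and inverting
`U + C ≈ S/(R*·a*)` estimates the number of active HSCs.

## Worked example

```r
library(hemaclone)

# synthetic deep-sequencing sample at the fitted macaque operating point
eff <- effective_params(a = 0.01, R = 70, eps_w = 5e-5)
h   <- sample_steady_state_reads(eff, C = 1e6, seed = 1)
fit <- fit_clone_mle(h, eps_w = 5e-5, grid_n = 13, C_total = 1e6)
fit
#> MLE of the stationary clone-size law (eps_w fixed at 5e-05)
#>   a* = 0.009893, R* = 70.54, logLik = -315897.66 (converged)
#>   active HSCs U+C ~ S/(R* a*) = 1000052 (S = 697870, 41368 clones observed)
```

Of the million marked clones, 41,368 were detected (the closed-form
expectation is `a·ln(εw/δ + 1) ≈ 4.3%`); the fit recovers the generating
parameters to about 1% (`a* = 0.0099` vs 0.01, `R* = 70.5` vs 70), and the
clone-count estimate `S/(R* a*)` recovers the million clones because every
clone here is marked and active. On real data, where the total clone count
is unknown, omit `C_total` and report the profile intervals
(`profile_loglik()`); at a representative deep-sequencing depth of `S = 10026` reads,
`(a*, R*) = (0.01, 70)` gives `U + C ≈ 14,300` active stem cells.

Other entry points: `simulate_clones()` (exact-event / tau-leap stochastic
simulator), `integrate_clone_dynamics()` (deterministic master-equation
transients), `sampled_clone_dist()` / `cumulative_F_and_Q()` (model
histograms and cumulative fractions), `load_clone_table()` /
`clone_size_histogram()` / `empirical_Q()` (data ingestion, rescaled
cumulative clone-fraction curves), `run_pipeline()` (config-driven simulate / fit / recover /
report runs). The methods vignette (`vignettes/clone-size-model.Rmd`)
documents the model, assumptions and numerical choices.

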