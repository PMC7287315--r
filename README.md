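# rhlpmix

Simultaneous clustering and segmentation of multi-subject time series with
mixtures of regressions with hidden logistic processes (mixRHLP).

Behavioral, physiological and sensor time series often exhibit two kinds of
*qualitative* structure at once: latent **clusters** of subjects that share
a dynamic signature, and latent **regimes** (phases) within each subject
that switch back and forth over time. `rhlpmix` is for researchers — e.g.
in education, psychology, or movement science — who want to extract both
from panels of univariate series on a shared time grid.

## The model

Subject `i` belongs to cluster `Z_i = k` with probability `α_k`. Given the
cluster, the regime at time `t_j` follows a multinomial logistic process

    π_kr(t_j) = exp(ω_kr0 + ω_kr1 t_j) / Σ_s exp(ω_ks0 + ω_ks1 t_j),

(reference regime pinned at zero), and the observation is Gaussian around a
regime-specific polynomial trend:
`y_i(t_j) | k, r ~ N(X_j β_kr, σ²_kr)` with `X_j = (1, t_j, …, t_j^d)`.
The observed-data log-likelihood

    l(Θ) = Σ_i log Σ_k α_k Π_j Σ_r π_kr(t_j) N(y_i(t_j); X_j β_kr, σ²_kr)

is maximized by a multi-start EM algorithm whose M-step combines weighted
least squares (for `β`, `σ²`) with an IRLS Newton loop on fractional regime
responsibilities (for `ω`). Candidate `(K, R, d)` structures are compared
by BIC, sample-adjusted BIC, AIC and AICc; posteriors give MAP cluster and
regime labels. A faithful generative simulator, an MCAR masking +
linear-imputation pipeline, label-matched accuracy/RMSE scoring, and a
Monte Carlo harness support method study; a preprocessing module (time
rescaling, interval aggregation, winsorization) prepares irregular
two-channel event streams.

## Worked example

Simulate the package's two-cluster, three-regime benchmark model at 20
subjects and 160 time points, mask 10% of cells at random, impute, fit the
generating structure, and score against the generating labels:

```r
library(rhlpmix)

truth <- benchmark_params(sigma = 0.1)
sim   <- simulate_rhlpmix(truth, n_subjects = 20, n_times = 160, seed = 42)
sim   <- apply_mcar(sim, pmiss = 0.1, seed = 43)
panel <- impute_linear(sim$data)

fit <- fit_rhlpmix(panel, model_spec(K = 2, R = 3, d = 1))
fit
#> mixRHLP fit: K = 2, R = 3, d = 1 (heteroskedastic)
#> log-likelihood -886.4191 after 33 EM iterations (converged), 27 parameters
#> criteria: BIC = 1990.75, saBIC = 1904.96, AIC = 1826.84, AICc = 1827.31

labels <- classify(fit, panel)
acc <- label_accuracy(sim$truth, labels, observed = sim$data$observed)
acc$cluster_acc   # fraction of subjects in their true cluster: 1
acc$regime_acc    # fraction of observed cells in their true regime: 0.9997

m   <- match_labels(sim$truth, labels, K = 2, R = 3)
est <- permute_params(fit$params, m)
round(rmse_by_group(list(est), truth), 4)
#> alpha_1  beta_0  beta_1   sigma omega_0 omega_1
#>  0.1500  0.0106  0.0244  0.0223  0.0548  0.2277
```

Every subject lands in its true cluster and 99.97% of the observed cells in
their true regime; the trend coefficients and residual sd are recovered to
a few hundredths (e.g. the estimated cluster-1 regime-1 trend is
`(0.0006, -1.498)` against a true `(0, -1.5)`). The `alpha_1` and switching
(`omega_*`) entries above are single-run errors at a small sample — they
shrink with more subjects and time points, which is exactly what the Monte
Carlo harness quantifies:

```r
meas <- summarize_runs(run_condition(100, 300, sigma = 0.1, pmiss = 0, M = 20))
meas$rmse    # all six parameter groups below 0.1 at N_p=100, N_t=300
```

Model selection over the default 32-candidate grid is
`select_models(panel)`; `rank_of(report, 2, 3, 1, "BIC")` gives the
generating model's rank. A thin command-line wrapper with `simulate`,
`fit`, `select`, `classify`, `preprocess` and `mcstudy` subcommands lives
at `inst/scripts/rhlpmix-cli.R`.

## Documentation

The methods vignette (`vignettes/rhlpmix-methods.Rmd`) describes the model
and its assumptions, the EM/IRLS updates, numerical safeguards, the
simulator's scope, and the package's design choices in detail.
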