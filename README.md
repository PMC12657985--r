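# ednatransfer

Joint Bayesian quantification of fish abundance from visual counts, water
eDNA and passive-air eDNA.

## The problem

During an upstream salmon migration, three very different instruments watch
the same biological signal: staff count fish accumulating below a ladder
gate, filtered river water yields eDNA copies by qPCR, and passive air
samplers (filters and an open water tray) collect the tiny aerosolized
fraction of that eDNA. Each stream alone is noisy and on its own scale.
`ednatransfer` fits the three streams **jointly** to one latent daily
fish-accumulation rate, which makes the cross-medium conversion factors —
how many eDNA copies per litre one fish per day produces, and how strongly
the air signal is diluted relative to water — estimable quantities with
honest uncertainty, rather than back-of-envelope ratios.

The package is aimed at molecular ecologists and biostatisticians designing
or analysing paired water/air eDNA surveys. It ships a forward simulator
with the model's exact generative structure, so the full pipeline is
testable without any field data.

## The model

With `t` indexing sampling dates, `j ∈ {gelatin, PTFE, MCE air, MCE DI
water}` the passive samplers and `b` biological replicates:

* **Counts** — effort `E_t` (days between gate openings, `E_1 = 0`)
  converts the latent rate `X_t` (fish/day) into an expected count
  `λ_t = X_t·E_t`, observed as `N_t ~ NegBinomial(λ_t, φ)` with fixed
  overdispersion `φ = 20` (variance `λ + λ²/φ`). Zero-effort dates carry no
  count likelihood.
* **Water** — `W_t = X_t·exp(ω)` copies/L, where `ω` (log scale) is the
  integrated eDNA factor aggregating shedding, decay, transport and
  dilution.
* **Air** — `ln A_tj = η_j + ln W_t + ε_tj`, a slope-one log-linear
  transfer with sampler-specific intercept `η_j` (the water-to-air
  dilution) and residual `ε_tj ~ N(0, τ_j)`. Duplicated samplers add
  replicate deviations `δ_tjb ~ N(0, ρ_j)` under a sum-to-zero constraint.
* **qPCR observation model**, shared between standards and environmental
  samples: a well holding `K` copies/µL amplifies with probability
  `ψ = 1 − exp(−K·θ)`; when it amplifies the Ct value is
  `Y ~ N(β₀ + β₁ₚ·ln K, exp(γ₀ + γ₁·ln K))` with plate-specific slopes
  `β₁ₚ`. Latent concentrations enter through the reaction normalizations
  `U_t = W_t·F/V` (water) and `Q_tjb = A_tjb·S·P/V` (air), with filtered
  volume `F`, collection surface `S`, deployment time `P` and reaction
  volume `V`.

Headline derived quantities: `exp(ω)` (copies/L per fish/day), per-sampler
capture efficiency `exp(η_j − η̄)` (geometric-mean-centred, product 1), and
dilution factors `exp(−η_j)`.

Posterior sampling uses JAGS (Gibbs/slice) behind a single canonical joint
log-density (`joint_log_density()`); diagnostics (rank-normalized split
R-hat, bulk ESS, posterior predictive checks, prior–posterior overlap) are
computed in the package.

## Worked example

```r
library(ednatransfer)

sim <- simulate_edna_dataset(sim_config(seed = 1))
sim
#> Synthetic joint eDNA dataset
#>   6 time points, 42 environmental samples, 164 qPCR wells
#>   wells: 32 standards, 18 water, 108 air, 6 controls

fit <- edna_fit(sim, n_chains = 4, n_warmup = 1000, n_sampling = 1000,
                seed = 1)
summary(fit)
#> Integrated eDNA factor omega (log scale): 9.626 [9.414, 9.829]
#>   => 15245 copies/L per fish/day [12253, 18564]
#>
#> Air samplers (transfer eta, residual tau, replicate rho, efficiency):
#>  sampler    eta eta_lower eta_upper   tau   rho efficiency ...
#>  gelatin -10.43     -11.1     -9.65 0.822 0.406      0.509
#>     ptfe  -9.30     -10.1     -8.50 0.850 0.115      1.571
#>  mce_air -10.74     -11.5     -9.93 0.863    NA      0.372
#>   mce_di  -8.22     -10.0     -6.17 2.300    NA      5.840
#>
#> Latent fish density: across-time mean 152.8 fish/day [126.0, 185.2]
#> Diagnostics: max R-hat 1.039, min ESS 116, 0 divergences (inspect)
```

The simulation used `ω = 9.578` and `η = (−10.45, −9.53, −10.91, −9.95)`;
the fit recovers the integrated eDNA factor (`exp(9.626) ≈ 15,245` copies/L
per fish/day against the generating `exp(9.578) ≈ 14,444`) and the transfer
intercepts within their credible intervals. The wide `mce_di` interval is
real: that sampler's transfer residual (`τ₄ = 1.78`) is by far the largest,
so six deployments constrain it loosely.

Point arithmetic on fitted transfer intercepts:

```r
capture_efficiency(c(-10.45, -9.53, -10.91, -9.95))
#> gelatin    ptfe mce_air  mce_di
#>   0.787   1.974   0.497   1.297     # product = 1 by construction

dilution_factor(c(-10.45, -9.53, -10.91, -9.95))$per_sampler
#> gelatin    ptfe mce_air  mce_di
#>   34544   13767   54721   20952     # air is ~14,000-55,000 x below water
```

`run_pipeline("out/")` chains simulate → fit → diagnose → summarize and
writes the input CSVs, `diagnostics.json`, a per-sampler `summary.csv`, the
latent trajectory and a reproducibility manifest.

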