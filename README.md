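# retentoKin

Kinetic modelling toolkit for glucose-limited continuous cultures of
recombinant protein-secreting yeast approaching zero growth. It is written
for bioprocess scientists who run chemostat ladders to estimate
maintenance-energy parameters and then push cultures into the retentostat
regime — full biomass retention behind a cell-retaining filter, so the
specific growth rate μ decays towards zero while secretion of the product
(here a single-domain antibody, VHH, from *Komagataella phaffii*)
continues.

Everything is organised around the Pirt partition of the biomass-specific
glucose uptake rate,

    q_S = μ / Y_XS^max + m_S + q_P / Y_PS^max ,

and four stages built on it:

1. **Chemostat estimation** — moving-window linear regression of
   growth-corrected q_S on μ over consecutive dilution-rate setpoints;
   window intercepts give m_S, reciprocal slopes give Y_XS^max, and the
   low-μ windows (μ ≤ 0.100 h⁻¹) are averaged into the prediction
   parameter set (`fit_pirt`).
2. **Forward retentostat simulation** — ODE model with closed-form
   declining feed (mixing-vessel kernel, 10 → 3.5 g/L glucose), full
   biomass retention, self-consistent μ ↔ q_P coupling and first-order
   product washout (`simulate_retentostat`).
3. **Retentostat regression** — bounded least-squares fit of the observed
   biomass accumulation profile with m_S as the single free parameter,
   returning the reconstructed μ(t), q_S(t) and the terminal growth rate
   (`fit_retentostat`).
4. **Product balance** — piecewise washout-corrected mass balance turning
   daily titer and biomass measurements into interval estimates of the
   specific productivity q_P, joined with interval growth rates to feed a
   Gompertz q_P(μ) = a·exp(−b·exp(−c·μ)) fit (`qp_series`,
   `fit_qp_gompertz`).

Seed-deterministic synthetic-data generators (`make_chemostat_dataset`,
`make_retentostat_observations`) emulate the experimental design — seven
setpoints spanning 0.015–0.170 h⁻¹, duplicate cultivations, 28-day
retentostats sampled every 24 h, multiplicative lognormal noise, ≥90 %
viability — so the entire pipeline is testable without bioreactor data.

## Worked example

```r
library(retentoKin)

## chemostat stage: 7 setpoints x 2 cultivations, 3% rate noise
d  <- make_chemostat_dataset(pirt_params(0.00437, 0.544),
                             qp_gompertz_default(),
                             noise = noise_spec(seed = 1))
cf <- fit_pirt(d)
cf
#> Moving-window Pirt regression of chemostat data
#>   7 setpoints, window = 3, 5 windows (3 at mu <= 0.1 h^-1)
#>   m_S      = 3.8 +/- 0.95 mg/g/h
#>   Y_XS_max = 0.5392 +/- 0.01 g/g

## retentostat stage: 28 days, daily sampling, viability declining to 0.90
cfg <- reactor_config()   # 1.4 L broth, 1.5 L mixing vessel, phi = 0.025 1/h
obs <- make_retentostat_observations(cfg, pirt_params(0.0037, 0.544),
                                     qp_gompertz_default(),
                                     noise = noise_spec(seed = 2))
rf  <- fit_retentostat(obs, cfg, cf$params, qp_model = qp_gompertz_default())
rf
#> Retentostat biomass-accumulation fit (least squares on m_S)
#>   signal: viable biomass, 29 observations over 672 h
#>   m_S         = 0.004157 g/g/h  (4.16 mg/g/h)
#>   terminal mu = 0.000323 1/h  (doubling time 89.4 days)
#>   residual SSE = 10.17 (g/L)^2
```

The chemostat fit recovers the generating maintenance coefficient
(4.37 mg/g/h) and maximum biomass yield (0.544 g/g) within the
window-to-window spread it reports. The retentostat fit reads off the
maintenance requirement of the near-zero-growth culture and its terminal
growth rate; the fitted-signal choice matters — here the fit tracks
*viable* biomass while the generator's viability declined to 0.90, which
is why the estimate sits above the generating 3.7 mg/g/h (with
`noise = no_noise()` the recovery is exact to machine precision).
`qp_mu_pairs(obs, cfg)` then yields the (μ, q_P) pairs for
`fit_qp_gompertz`, and `run_pipeline(out_dir, seed)` chains all stages and
writes every intermediate plus a summary and manifest.

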