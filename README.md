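# occuhet

Movement-driven detection heterogeneity in single-season occupancy models.

Occupancy models estimate the proportion of sites occupied by a species,
ψ, from repeat-visit detection-nondetection data, assuming a constant
per-visit detection probability *p* at occupied sites. Two spatial processes
violate that assumption without any covariate signal: the random position of
each bird's territory relative to the survey point, and within-territory
movement. Both make detections-per-site distributions overdispersed
("flat"), which biases occupancy estimates — a problem that grows acute for
point counts and passive acoustic monitoring (PAM), and that many-visit PAM
detection histories can diagnose. `occuhet` is for ornithologists and
biostatisticians who want to simulate that process, fit models that do and
do not accommodate it, test for it, and quantify the bias.

The package provides:

* **An agent-based simulator** of auditory point-count visits: territory
  centres placed at density *D* on a 1.5 × 1.5 km landscape, relocations at
  exponential times with bivariate-normal positions (per-axis SD σₘ) around
  the centre, Poisson cue production (ν = 0.25 min⁻¹), and half-normal
  perceptibility g(d) = exp(−(d/τ)²) with effective detection radius
  τ = 60 m. A site is occupied when some bird's core territory (radius 2σₘ)
  overlaps the sampled circle (radius τ√log(1/0.06) ≈ 100 m). The event
  loop is compiled (Rcpp), so full scenario grids are desk-scale.
* **Three covariate-free maximum-likelihood estimators** of the
  detections-per-site distribution Dᵢ over N visits:
  the **basic** zero-inflated binomial, Dᵢ ~ ZI-Binomial(N, p; 1−ψ);
  the **ZIBB** zero-inflated beta-binomial, pᵢ ~ Beta(α, β);
  and **Royle-Nichols**, Bᵢ ~ Poisson(λ), pᵢ = 1−(1−r)^{Bᵢ}, with derived
  occupancy ψ = 1−e^{−λ}.
* **Exact tests**: site-level detection heterogeneity against a binomial
  (or, without truth flags, zero-truncated binomial) null, and goodness of
  fit of each fitted model's expected Dᵢ distribution — both as Fisher's
  exact test on the observed-vs-expected table (Monte Carlo p-values), with
  a one-sample exact multinomial alternative.
* **An experiment harness** (`run_grid()`) crossing density, territory
  size and occupancy, recording bias, CI coverage and width, boundary rates
  and test outcomes as the number of visits per site varies.

## Worked example

Simulate one scenario (0.5 birds ha⁻¹, σₘ = 25 m, 80% of 200 sites
occupied, 20 visits), test it, and fit all three models:

```r
library(occuhet)

cfg <- scenario_config(density = 0.5, movement_sd = 25, psi = 0.8,
                       n_sites = 200, n_visits = 20, seed = 42)
h <- simulate_scenario(cfg)
h
#> detection_history: 200 sites x 20 visits; naive occupancy 0.800; true fraction occupied 0.800

heterogeneity_test(h, mode = "simulated")
#> detection heterogeneity (simulated mode): P = 0.0001 (MC error 0.0001, 10000 tables) -> flagged at alpha = 0.05

fit_basic(h)
#> occu_fit [basic]: psi_hat = 0.8000, p = 0.6334, loglik = -896.928
fit_rn(h)
#> occu_fit [rn]: psi_hat = 0.8881, lambda = 2.1905, r = 0.3657, loglik = -608.277
fit_zibb(h)
#> occu_fit [zibb]: psi_hat = 0.8085, alpha = 1.5908, beta = 0.9679, loglik = -568.386
```

Detection probabilities vary strongly between sites (the heterogeneity test
rejects the constant-*p* binomial at P < 0.05). With the full 20 visits the
basic model still lands on the truth here (error 0.0 points) because every
occupied site was eventually detected; the Royle-Nichols model overestimates
(+8.8 points), reading the flat detection distribution as extra abundance;
the ZIBB model absorbs the heterogeneity into its beta law (+0.8 points) and
is the only one passing the goodness-of-fit test:

```r
gof_test(fit_basic(h), h)
#> goodness of fit (basic model): P = 0.0001 (...) -> flagged at alpha = 0.05
gof_test(fit_rn(h), h)
#> goodness of fit (rn model): P = 0.0048 (...) -> flagged at alpha = 0.05
gof_test(fit_zibb(h), h)
#> goodness of fit (zibb model): P = 0.9381 (...) -> not flagged
```

Short histories are where the bias lives: truncated to the first two visits,
naive occupancy drops to 0.66 and the basic model follows it down:

```r
h2 <- subsample_visits(h, 2)
fit_basic(h2)$estimates[["psi"]]
#> [1] 0.72        # truth is 0.80
```

`run_grid()` repeats this over the 90-scenario design (6 densities × 5
movement SDs × 3 occupancy levels) and `summarize_grid()` aggregates errors
(in points and relative to truth), coverage, boundary rates and test
failure rates per model and visit length; see the package vignette for the
full design.

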