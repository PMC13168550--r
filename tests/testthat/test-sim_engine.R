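test_that("half-normal perceptibility matches its anchors and is monotone", {
  expect_equal(perceptibility(50, 60), exp(-(50 / 60)^2))
  expect_equal(round(perceptibility(50, 60), 4), 0.4994)
  expect_equal(round(perceptibility(100, 60), 4), 0.0622)
  expect_identical(perceptibility(0, 60), 1)
  d <- seq(0, 300, by = 1)
  expect_true(all(diff(perceptibility(d, 60)) < 0))
  expect_true(all(perceptibility(d, 60) > 0 & perceptibility(d, 60) <= 1))
  expect_error(perceptibility(50, 0), "edr")
  expect_error(perceptibility(-1, 60), "distance")
})

test_that("sampling radius inverts perceptibility at the 6% floor", {
  for (edr in c(60, 90, 120)) {
    r <- sampling_radius(edr)
    expect_equal(perceptibility(r, edr), 0.06, tolerance = 1e-9)
  }
  expect_equal(sampling_radius(60), 100, tolerance = 0.01)
  expect_equal(sampling_radius(120), 2 * sampling_radius(60))
  # numeric root-find oracle at 90 m
  root <- uniroot(function(d) perceptibility(d, 90) - 0.06, c(0, 1000),
                  tol = 1e-12)$root
  expect_equal(sampling_radius(90), root, tolerance = 1e-8)
})

test_that("core-territory areas reproduce the movement-SD ladder", {
  areas <- core_territory_area(c(0, 10, 25, 50, 100))
  expect_equal(areas[1], 0)
  expect_equal(round(areas, 2), c(0, 0.13, 0.79, 3.14, 12.57))
})

test_that("territory placement draws Poisson counts and respects spacing", {
  cfg <- scenario_config(density = 0.1, movement_sd = 0, seed = 1)
  set.seed(11)
  n <- replicate(2000, nrow(place_territories(cfg)))
  # density 0.1 ha^-1 on 225 ha: Poisson mean 22.5
  expect_lt(abs(mean(n) - 22.5), 3 * sqrt(22.5 / 2000))
  cfg0 <- scenario_config(density = 0, movement_sd = 0)
  expect_identical(nrow(place_territories(cfg0)), 0L)
  # hard-core option: min pairwise distance >= inhibition radius
  set.seed(12)
  b <- place_territories(cfg, spacing = "inhibition")
  if (attr(b, "n_fallback") == 0 && nrow(b) > 1) {
    dmin <- min(dist(cbind(b$x, b$y)))
    expect_gte(dmin, 0.5 * sqrt(1 / 0.1) * 100)
  }
  # infeasible hard-core spacing falls back with a warning
  cfg_hi <- scenario_config(density = 2, movement_sd = 0)
  set.seed(13)
  expect_warning(place_territories(cfg_hi, spacing = "inhibition",
                                   max_attempts = 1),
                 "unconstrained")
})

test_that("site occupancy uses sampling radius plus two movement SDs", {
  mk <- function(dist, sd) {
    cfg <- scenario_config(movement_sd = sd)
    list(birds = data.frame(x = 750 + dist, y = 750), cfg = cfg)
  }
  a <- mk(99, 0)
  expect_true(site_occupied(a$birds, a$cfg))
  b <- mk(151, 25)
  expect_false(site_occupied(b$birds, b$cfg))
  cfg <- scenario_config()
  expect_false(site_occupied(data.frame(x = numeric(0), y = numeric(0)), cfg))
})

test_that("visit detection frequency matches the thinned-Poisson closed form", {
  set.seed(21)
  n <- 20000L
  for (d in c(0, 50, 100)) {
    emp <- mean(visits_cpp(750 + d, 750, 0, n))
    theo <- stationary_detect_prob(d)
    expect_lt(abs(emp - theo), 3 * sqrt(theo * (1 - theo) / n))
  }
  # two stationary birds detected independently
  emp2 <- mean(visits_cpp(c(780, 750), c(750, 830), 0, n))
  theo2 <- stationary_detect_prob(c(30, 80))
  expect_lt(abs(emp2 - theo2), 3 * sqrt(theo2 * (1 - theo2) / n))
  # event-logged R path agrees with the same closed form
  cfg <- scenario_config(exactly_one = TRUE, movement_sd = 0)
  birds <- data.frame(x = 750 + 50, y = 750)
  emp_r <- mean(replicate(4000, simulate_visit(birds, cfg)$detected))
  theo_r <- stationary_detect_prob(50)
  expect_lt(abs(emp_r - theo_r), 3 * sqrt(theo_r * (1 - theo_r) / 4000))
})

test_that("no birds means no detections and cue logs are consistent", {
  cfg <- scenario_config()
  none <- data.frame(x = numeric(0), y = numeric(0))
  expect_identical(simulate_visit(none, cfg)$detected, 0L)
  set.seed(31)
  birds <- data.frame(x = c(760, 700), y = c(750, 790))
  v <- simulate_visit(birds, cfg, cue_log = TRUE)
  expect_identical(v$detected, as.integer(any(v$cue_log$detected)))
  expect_true(all(v$cue_log$time >= 0 & v$cue_log$time <= cfg$duration))
})

test_that("cue counts per visit are Poisson with mean cue_rate x duration", {
  cfg <- scenario_config(exactly_one = TRUE, movement_sd = 10)
  birds <- data.frame(x = 750, y = 750)
  set.seed(41)
  counts <- replicate(4000, nrow(simulate_visit(birds, cfg,
                                                cue_log = TRUE)$cue_log))
  mu <- cfg$cue_rate * cfg$duration
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 4000))
  expect_lt(abs(var(counts) - mu), 3 * mu * sqrt(2 / 4000))
})

test_that("simulated sites are occupied and exactly_one nests lie in range", {
  set.seed(51)
  cfg <- scenario_config(exactly_one = TRUE, movement_sd = 0, n_visits = 5)
  for (i in 1:20) {
    s <- simulate_site(cfg)
    expect_true(site_occupied(s$birds, cfg))
    d <- sqrt((s$birds$x - 750)^2 + (s$birds$y - 750)^2)
    expect_lt(min(d), sampling_radius(60))
    expect_length(s$detections, 5)
  }
})

test_that("scenario histories have the promised structure and determinism", {
  cfg <- scenario_config(density = 0.25, movement_sd = 25, psi = 0.5,
                         n_sites = 40, n_visits = 6, seed = 99)
  h1 <- simulate_scenario(cfg)
  h2 <- simulate_scenario(cfg)
  expect_identical(h1$y, h2$y)
  expect_identical(sum(h1$z), 20L)
  expect_true(all(rowSums(h1$y[!h1$z, , drop = FALSE]) == 0))
  expect_identical(site_counts(h1), as.integer(rowSums(h1$y)))
  # occupied fraction is exactly round(psi * M) / M
  cfg2 <- scenario_config(density = 0.25, psi = 0.33, n_sites = 40,
                          n_visits = 4, seed = 1)
  expect_identical(sum(simulate_scenario(cfg2)$z), 13L)
})

test_that("single stationary bird gives the binomial placement mixture", {
  # psi = 1, exactly_one, sd = 0: D | nest distance d ~ Binomial(N, p(d)),
  # nest uniform on the sampling disc; oracle by numeric integration
  N <- 5
  R <- sampling_radius(60)
  pmf_oracle <- vapply(0:N, function(k) {
    integrate(function(d) 2 * d / R^2 *
                dbinom(k, N, 1 - exp(-2.5 * exp(-(d / 60)^2))),
              0, R, rel.tol = 1e-9)$value
  }, numeric(1))
  cfg <- scenario_config(exactly_one = TRUE, movement_sd = 0, psi = 1,
                         n_sites = 2000, n_visits = N, seed = 7)
  h <- simulate_scenario(cfg)
  emp <- tabulate(site_counts(h) + 1L, N + 1L) / 2000
  se <- sqrt(pmf_oracle * (1 - pmf_oracle) / 2000)
  expect_true(all(abs(emp - pmf_oracle) < 3.5 * se + 1e-3))
})

test_that("beta-heterogeneous generator honours occupancy and truth flags", {
  h <- simulate_beta_history(100, 8, psi = 0.6, seed = 5)
  expect_identical(sum(h$z), 60L)
  expect_true(all(rowSums(h$y[!h$z, ]) == 0))
  h2 <- simulate_beta_history(100, 8, psi = 0.6, seed = 5)
  expect_identical(h$y, h2$y)
})
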