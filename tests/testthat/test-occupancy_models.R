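test_that("zero-inflated binomial log-likelihood is a proper distribution", {
  # enumeration oracle: probabilities over all D configurations sum to 1
  for (psi in c(0.3, 1)) {
    tot <- sum(vapply(0:2, function(d) exp(loglik_basic(psi, 0.7, d, 2)),
                      numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
  # psi = 1 reduces to the plain binomial log-likelihood
  D <- c(0, 1, 3, 2)
  expect_equal(loglik_basic(1, 0.4, D, 3),
               sum(dbinom(D, 3, 0.4, log = TRUE)))
  expect_identical(loglik_basic(0, 0.4, c(0, 0), 3), 0)
  expect_identical(loglik_basic(1.2, 0.4, D, 3), -Inf)
})

test_that("basic model recovers trivial and simulated generating values", {
  # all-or-nothing counts pin psi at the detected fraction and p at 1
  D <- c(rep(10L, 30), rep(0L, 70))
  f <- fit_basic(D, N = 10)
  expect_equal(f$estimates[["psi"]], 0.3, tolerance = 1e-3)
  expect_gt(f$estimates[["p"]], 0.995)
  # parameter recovery within 3 SEs on self-generated data
  set.seed(61)
  D2 <- rbinom(2000, 10, 0.4) * rbinom(2000, 1, 0.6)
  f2 <- fit_basic(D2, N = 10)
  expect_lt(abs(f2$transformed[["logit_psi"]] - qlogis(0.6)),
            3 * f2$se[["se_logit_psi"]])
  expect_lt(abs(f2$transformed[["logit_p"]] - qlogis(0.4)),
            3 * f2$se[["se_logit_p"]])
  expect_error(fit_basic(rep(0L, 10), N = 5), "no detections")
})

test_that("weighted expected-frequency fits reproduce generating parameters", {
  # homogeneous two-visit landscape: psi = 0.5, p = 0.8 recovered exactly
  probs <- 0.5 * dbinom(0:2, 2, 0.8) + 0.5 * c(1, 0, 0)
  f <- fit_basic(0:2, N = 2, weights = 200 * probs)
  expect_equal(f$estimates[["psi"]], 0.5, tolerance = 1e-4)
  expect_equal(f$estimates[["p"]], 0.8, tolerance = 1e-4)
  # heterogeneous ten-visit landscape: ZIBB recovers psi and both shapes
  bb <- function(d, N, a, b) choose(N, d) * beta(a + d, b + N - d) / beta(a, b)
  probs2 <- 0.8 * bb(0:10, 10, 0.4, 0.4) + 0.2 * c(1, rep(0, 10))
  set.seed(62)
  fz <- fit_zibb(0:10, N = 10, weights = 200 * probs2)
  expect_equal(fz$estimates[["psi"]], 0.8, tolerance = 0.02)
  expect_equal(fz$estimates[["alpha"]], 0.4, tolerance = 0.02)
  expect_equal(fz$estimates[["beta"]], 0.4, tolerance = 0.02)
})

test_that("the beta-binomial nests the binomial and flags boundary fits", {
  set.seed(63)
  D <- rbinom(500, 10, 0.35) * rbinom(500, 1, 0.7)
  fb <- fit_basic(D, N = 10)
  fz <- suppressWarnings(fit_zibb(D, N = 10))
  expect_gte(fz$loglik, fb$loglik - 1e-6)
  # all sites detected: psi is pushed to the boundary
  set.seed(64)
  Dall <- pmax(rbinom(200, 10, rbeta(200, 5, 5)), 1)
  fz2 <- fit_zibb(Dall, N = 10)
  expect_gt(fz2$estimates[["psi"]], 0.99)
  expect_true(fz2$boundary)
  expect_warning(fit_zibb(c(0, 1, 2, 1, 0), N = 2), "weakly identified")
})

test_that("Royle-Nichols occupancy is derived from lambda and K is stable", {
  h <- simulate_beta_history(200, 10, psi = 0.8, seed = 65)
  f <- fit_rn(h)
  expect_identical(f$estimates[["psi"]], 1 - exp(-f$estimates[["lambda"]]))
  f2 <- fit_rn(h, K = 2 * f$K)
  expect_lt(abs(f$loglik - f2$loglik), 1e-6)
  expect_true(any(grepl("doubling", capture_warnings(fit_rn(h, K = 1)))))
  # parameter recovery on self-generated data
  set.seed(66)
  B <- rpois(2000, 1.1)
  D <- rbinom(2000, 10, 1 - (1 - 0.3)^B)
  fr <- fit_rn(D, N = 10)
  expect_lt(abs(fr$transformed[["log_lambda"]] - log(1.1)),
            3 * fr$se[["se_log_lambda"]])
  expect_lt(abs(fr$transformed[["logit_r"]] - qlogis(0.3)),
            3 * fr$se[["se_logit_r"]])
})

test_that("expected detections-per-site distributions match their oracles", {
  fb <- fit_basic(c(rep(2L, 2), rep(0L, 1), 1L), N = 2)
  fb$estimates <- c(psi = 1, p = 0.5)
  expect_equal(as.numeric(expected_distribution(fb, 4, 2)), c(1, 2, 1))
  # Beta(1, 1) site probabilities make detections uniform on 0..N
  fz <- fit_basic(c(0L, 1L, 2L), N = 2)
  fz$model <- "zibb"
  fz$estimates <- c(psi = 1, alpha = 1, beta = 1)
  expect_equal(as.numeric(expected_distribution(fz, 12, 3)), rep(3, 4),
               tolerance = 1e-9)
  # RN mixture vs simulation oracle
  set.seed(67)
  lam <- 1.2; r <- 0.35; N <- 6
  B <- rpois(2e5, lam)
  emp <- tabulate(rbinom(2e5, N, 1 - (1 - r)^B) + 1L, N + 1L) / 2e5
  fr <- fit_rn(simulate_beta_history(50, N, psi = 1, seed = 1))
  fr$estimates <- c(psi = 1 - exp(-lam), lambda = lam, r = r)
  theo <- as.numeric(expected_distribution(fr, 1, N))
  expect_true(all(abs(emp - theo) < 3 * sqrt(theo * (1 - theo) / 2e5) + 1e-3))
  expect_equal(sum(expected_distribution(fr, 200, N)), 200, tolerance = 1e-6)
})

test_that("Wald intervals are ordered, bounded, and honest about failure", {
  h <- simulate_beta_history(200, 10, psi = 0.8, seed = 68)
  for (f in list(fit_basic(h), suppressWarnings(fit_zibb(h)), fit_rn(h))) {
    ci <- wald_ci(f)
    expect_true(attr(ci, "available"))
    expect_lte(ci[["lower"]], f$estimates[["psi"]])
    expect_gte(ci[["upper"]], f$estimates[["psi"]])
    expect_true(all(ci >= 0 & ci <= 1))
  }
  f <- fit_basic(h)
  f$se[1] <- NA_real_
  ci <- wald_ci(f)
  expect_false(attr(ci, "available"))
  expect_true(all(is.na(ci)))
})

test_that("likelihoods depend on the history only through site counts", {
  h <- simulate_beta_history(120, 8, psi = 0.7, seed = 69)
  perm <- detection_history(h$y[sample(nrow(h$y)), ], NULL, NULL)
  shuf <- detection_history(t(apply(h$y, 1, sample)), NULL, NULL)
  base <- detection_history(h$y, NULL, NULL)
  for (fitter in list(fit_basic, fit_rn)) {
    expect_equal(fitter(perm)$loglik, fitter(base)$loglik, tolerance = 1e-6)
    expect_equal(fitter(shuf)$loglik, fitter(base)$loglik, tolerance = 1e-6)
  }
})

test_that("fit serialization round-trips through JSON", {
  f <- fit_basic(simulate_beta_history(100, 6, psi = 0.5, seed = 70))
  path <- tempfile(fileext = ".json")
  write_fit(f, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$estimates$psi, f$estimates[["psi"]])
  expect_equal(back$loglik, f$loglik)
  expect_identical(back$model, "basic")
})
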