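# Covariate-free maximum-likelihood fitting of the three occupancy models.
# All likelihoods act on the per-site detection counts D_i (sufficient under
# constant-within-site per-visit probability) with optional site weights, so
# the same code fits observed histories and analytic expected-frequency
# tables.

resolve_counts <- function(x, N = NULL, weights = NULL) {
  if (inherits(x, "detection_history")) {
    D <- site_counts(x)
    N <- n_visits(x)
  } else {
    D <- as.numeric(x)
    if (is.null(N)) stop("`N` (visits) is required when `x` is a count vector")
  }
  if (any(D < 0 | D > N)) stop("counts must lie in [0, N]")
  if (is.null(weights)) weights <- rep(1, length(D))
  if (length(weights) != length(D)) stop("`weights` must match `x` in length")
  # collapse to unique counts: the likelihoods depend on the data only
  # through D, so summing weights within counts is exact and much faster
  ud <- sort(unique(D))
  wd <- vapply(ud, function(d) sum(weights[D == d]), numeric(1))
  list(D = ud, N = as.integer(N), w = wd)
}

#' Zero-inflated binomial log-likelihood
#'
#' Log-likelihood of occupancy probability `psi` and constant per-visit
#' detection probability `p` for detections-per-site counts:
#' `sum_i log[ psi * C(N, D_i) p^D_i (1-p)^(N-D_i) + (1-psi) 1{D_i = 0} ]`.
#' Out-of-range parameters return `-Inf` rather than erroring.
#'
#' @param psi Occupancy probability.
#' @param p Per-visit detection probability.
#' @param D Detections-per-site counts.
#' @param N Number of visits.
#' @param weights Optional per-site weights (defaults to 1).
#' @return Log-likelihood (scalar).
#' @export
loglik_basic <- function(psi, p, D, N, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(D))
  if (psi < 0 || psi > 1 || p < 0 || p > 1) return(-Inf)
  sum(weights * log(psi * dbinom(D, N, p) + (1 - psi) * (D == 0)))
}

# log beta-binomial pmf via log-gamma; for very large alpha + beta the
# log-gamma differences cancel catastrophically, so switch to the binomial
# limit with p = alpha / (alpha + beta)
lbetabinom <- function(d, N, a, b) {
  if (a + b > 1e10) return(dbinom(d, N, a / (a + b), log = TRUE))
  lchoose(N, d) + lbeta(a + d, b + N - d) - lbeta(a, b)
}

loglik_zibb_counts <- function(psi, a, b, D, N, w) {
  if (psi < 0 || psi > 1 || a <= 0 || b <= 0 ||
      !is.finite(a) || !is.finite(b)) return(-Inf)
  sum(w * log(psi * exp(lbetabinom(D, N, a, b)) + (1 - psi) * (D == 0)))
}

loglik_rn_counts <- function(lambda, r, D, N, w, K) {
  if (lambda < 0 || r < 0 || r > 1 || !is.finite(lambda) ||
      lambda > 100 * K) return(-Inf)
  B <- 0:K
  lpois <- dpois(B, lambda, log = TRUE)
  pB <- 1 - (1 - r)^B
  # sites x B matrix of log P(D_i | B) + log P(B)
  lmat <- outer(D, pB, function(d, p) dbinom(d, N, p, log = TRUE))
  lmat <- sweep(lmat, 2, lpois, "+")
  mx <- apply(lmat, 1, max)
  ll <- mx + log(rowSums(exp(lmat - mx)))
  sum(w * ll)
}

check_fittable <- function(cc) {
  if (sum(cc$w[cc$D > 0]) == 0)
    stop("degenerate history: no detections; occupancy models are not identifiable")
  if (all(cc$D[cc$w > 0] == cc$N))
    stop("degenerate history: every site detected on every visit")
}

# shared quasi-Newton driver: smart start + seeded random restarts
ml_optimise <- function(nll, start, n_restarts = 5, restart_sd = 1.5) {
  best <- NULL
  starts <- c(list(start),
              lapply(seq_len(n_restarts - 1),
                     function(i) start + rnorm(length(start), 0, restart_sd)))
  for (st in starts) {
    o <- tryCatch(optim(st, nll, method = "BFGS",
                        control = list(reltol = 1e-10, maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value) &&
        (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best
}

se_from_hessian <- function(nll, par) {
  H <- tryCatch(optimHess(par, nll), error = function(e) NULL)
  if (is.null(H)) return(list(se = rep(NA_real_, length(par)), vcov = NULL))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0))
    return(list(se = rep(NA_real_, length(par)), vcov = V))
  list(se = sqrt(diag(V)), vcov = V)
}

new_occu_fit <- function(model, estimates, transformed, se, vcov, loglik,
                         converged, extra = list()) {
  structure(c(list(model = model, estimates = estimates,
                   transformed = transformed, se = se, vcov = vcov,
                   loglik = loglik, converged = converged,
                   boundary = estimates[["psi"]] > 0.99), extra),
            class = "occu_fit")
}

#' @export
print.occu_fit <- function(x, ...) {
  extra <- setdiff(names(x$estimates), "psi")
  cat(sprintf("occu_fit [%s]: psi_hat = %.4f%s, loglik = %.3f%s%s\n",
              x$model, x$estimates[["psi"]],
              paste(sprintf(", %s = %.4f", extra,
                            unlist(x$estimates[extra])), collapse = ""),
              x$loglik,
              if (!x$converged) " [not converged]" else "",
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Fit the basic zero-inflated binomial occupancy model
#'
#' Maximum-likelihood fit of the single-season, covariate-free occupancy
#' model `D_i ~ ZI-Binomial(N, p; zero-inflation 1 - psi)` on the
#' (logit psi, logit p) scale by quasi-Newton with seeded random restarts;
#' SEs from the inverse numerical Hessian.
#'
#' @param x A [detection_history()] or a vector of detections-per-site
#'   counts.
#' @param N Number of visits (required when `x` is a count vector).
#' @param weights Optional per-site weights (e.g. expected cell frequencies).
#' @return An `occu_fit` with elements `estimates` (`psi`, `p`),
#'   `transformed` and `se` on the logit scale, `loglik`, `converged` and
#'   `boundary` (`psi > 0.99`) flags.
#' @export
#' @examples
#' h <- simulate_beta_history(200, 10, psi = 0.8, seed = 1)
#' fit_basic(h)
fit_basic <- function(x, N = NULL, weights = NULL) {
  cc <- resolve_counts(x, N, weights)
  check_fittable(cc)
  nll <- function(th)
    -loglik_basic(plogis(th[1]), plogis(th[2]), cc$D, cc$N, cc$w)
  naive <- sum(cc$w[cc$D > 0]) / sum(cc$w)
  p0 <- sum(cc$w * cc$D) / (cc$N * sum(cc$w)) / max(naive, 0.05)
  start <- qlogis(pmin(pmax(c(naive, p0), 0.02), 0.98))
  best <- ml_optimise(nll, start)
  ses <- se_from_hessian(nll, best$par)
  new_occu_fit("basic",
               c(psi = plogis(best$par[1]), p = plogis(best$par[2])),
               c(logit_psi = best$par[1], logit_p = best$par[2]),
               c(se_logit_psi = ses$se[1], se_logit_p = ses$se[2]),
               ses$vcov, -best$value, best$convergence == 0)
}

#' Fit the zero-inflated beta-binomial (ZIBB) occupancy model
#'
#' Site detection probability is a beta draw, `p_i ~ Beta(alpha, beta)`, and
#' `D_i | occupied ~ Beta-Binomial(N, alpha, beta)` with zero inflation
#' `1 - psi`. Fitted by ML on (logit psi, log alpha, log beta). Fits to
#' 2-visit histories are attempted with a warning: three parameters are then
#' weakly identified.
#'
#' @inheritParams fit_basic
#' @return An `occu_fit` with `estimates` (`psi`, `alpha`, `beta`).
#' @export
fit_zibb <- function(x, N = NULL, weights = NULL) {
  cc <- resolve_counts(x, N, weights)
  check_fittable(cc)
  if (cc$N < 3)
    warning("ZIBB with fewer than 3 visits is weakly identified (3 parameters)")
  # log alpha, log beta capped at 30 (alpha + beta ~ 1e13 is already in the
  # binomial-limit branch of the pmf), keeping the estimates finite
  nll <- function(th)
    -loglik_zibb_counts(plogis(th[1]), exp(min(th[2], 30)),
                        exp(min(th[3], 30)), cc$D, cc$N, cc$w)
  naive <- sum(cc$w[cc$D > 0]) / sum(cc$w)
  start <- c(qlogis(pmin(pmax(naive * 1.1, 0.05), 0.95)), 0, 0)
  best <- ml_optimise(nll, start)
  # the binomial limit (alpha, beta -> Inf at fixed mean) is a flat ridge the
  # quasi-Newton steps can stall on; offer the profiled limit of the basic
  # fit as a further start and keep whichever is better
  basic0 <- tryCatch(fit_basic(cc$D, cc$N, cc$w), error = function(e) NULL)
  if (!is.null(basic0)) {
    lim_start <- c(basic0$transformed[["logit_psi"]],
                   log(1e12 * basic0$estimates[["p"]]),
                   log(1e12 * (1 - basic0$estimates[["p"]])))
    lim <- tryCatch(optim(lim_start, nll, method = "BFGS",
                          control = list(reltol = 1e-10, maxit = 500)),
                    error = function(e) NULL)
    # tie-break: on an exactly flat ridge (e.g. 2-visit histories) keep the
    # interior heterogeneous optimum; take the limit only when genuinely
    # better than the convergence tolerance
    if (!is.null(lim) && is.finite(lim$value) &&
        lim$value < best$value - 1e-6)
      best <- lim
  }
  ses <- se_from_hessian(nll, best$par)
  best$par[2:3] <- pmin(best$par[2:3], 30)
  new_occu_fit("zibb",
               c(psi = plogis(best$par[1]), alpha = exp(best$par[2]),
                 beta = exp(best$par[3])),
               c(logit_psi = best$par[1], log_alpha = best$par[2],
                 log_beta = best$par[3]),
               c(se_logit_psi = ses$se[1], se_log_alpha = ses$se[2],
                 se_log_beta = ses$se[3]),
               ses$vcov, -best$value, best$convergence == 0)
}

#' Fit the Royle-Nichols abundance-induced detectability model
#'
#' Latent site abundance `B_i ~ Poisson(lambda)` with per-individual
#' detection probability `r`; the site detection probability is
#' `p_i = 1 - (1 - r)^B_i` and `D_i ~ Binomial(N, p_i)`. The Poisson sum is
#' truncated at `K` (auto-doubled, with a warning, while the tail mass at the
#' fitted lambda exceeds 1e-8). Occupancy is derived as
#' `psi = 1 - exp(-lambda)`, one minus the probability that a site holds no
#' individuals.
#'
#' @inheritParams fit_basic
#' @param K Truncation point of the latent-abundance sum.
#' @return An `occu_fit` with `estimates` (`psi`, `lambda`, `r`) and the
#'   truncation `K` used. `se` holds SEs of (log lambda, logit r); the SE of
#'   the derived occupancy follows by the delta method on log lambda.
#' @export
fit_rn <- function(x, N = NULL, weights = NULL, K = 60) {
  cc <- resolve_counts(x, N, weights)
  check_fittable(cc)
  stopifnot(K >= 1)
  repeat {
    nll <- function(th)
      -loglik_rn_counts(exp(th[1]), plogis(th[2]), cc$D, cc$N, cc$w, K)
    naive <- sum(cc$w[cc$D > 0]) / sum(cc$w)
    lam0 <- -log(1 - pmin(pmax(naive, 0.05), 0.95))
    start <- c(log(lam0), qlogis(0.3))
    best <- ml_optimise(nll, start)
    lam_hat <- exp(best$par[1])
    if (ppois(K, lam_hat, lower.tail = FALSE) <= 1e-8) break
    warning(sprintf("RN truncation K = %d too small at lambda = %.2f; doubling",
                    K, lam_hat))
    K <- 2L * K
  }
  ses <- se_from_hessian(nll, best$par)
  new_occu_fit("rn",
               c(psi = 1 - exp(-lam_hat), lambda = lam_hat,
                 r = plogis(best$par[2])),
               c(log_lambda = best$par[1], logit_r = best$par[2]),
               c(se_log_lambda = ses$se[1], se_logit_r = ses$se[2]),
               ses$vcov, -best$value, best$convergence == 0,
               extra = list(K = K))
}

#' Expected detections-per-site distribution under a fitted model
#'
#' Expected number of sites (out of `M`) with each count `D` in `0..N` under
#' the fitted model: zero-inflated binomial, zero-inflated beta-binomial, or
#' the Royle-Nichols Poisson mixture over latent abundance. Sums to `M`
#' (within truncation error `< 1e-6` for RN).
#'
#' @param fit An `occu_fit`.
#' @param M Number of sites.
#' @param N Number of visits.
#' @return Numeric vector of length `N + 1`, names `"0"..."N"`.
#' @export
expected_distribution <- function(fit, M, N) {
  stopifnot(inherits(fit, "occu_fit"))
  d <- 0:N
  est <- fit$estimates
  pm <- switch(fit$model,
    basic = est[["psi"]] * dbinom(d, N, est[["p"]]) +
      (1 - est[["psi"]]) * (d == 0),
    zibb = est[["psi"]] * exp(lbetabinom(d, N, est[["alpha"]],
                                         est[["beta"]])) +
      (1 - est[["psi"]]) * (d == 0),
    rn = {
      B <- 0:fit$K
      w <- dpois(B, est[["lambda"]])
      pB <- 1 - (1 - est[["r"]])^B
      as.numeric(vapply(d, function(k) sum(w * dbinom(k, N, pB)), 0)) /
        sum(w)
    },
    stop("unknown model: ", fit$model))
  stats::setNames(M * pm, d)
}

#' Wald confidence interval for occupancy
#'
#' Wald interval on the transformed scale, back-transformed to `[0, 1]`: on
#' logit psi for the basic and ZIBB models, on log lambda for the
#' Royle-Nichols model (then mapped through `psi = 1 - exp(-lambda)`). When
#' the Hessian-based SE is unavailable the interval is marked unavailable.
#'
#' @param fit An `occu_fit`.
#' @param level Coverage level.
#' @return Numeric `c(lower, upper)` with attribute `available`.
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "occu_fit"))
  z <- qnorm(1 - (1 - level) / 2)
  se1 <- fit$se[[1]]
  if (is.na(se1)) {
    out <- c(lower = NA_real_, upper = NA_real_)
    attr(out, "available") <- FALSE
    return(out)
  }
  if (fit$model == "rn") {
    ll <- fit$transformed[["log_lambda"]]
    out <- c(lower = 1 - exp(-exp(ll - z * se1)),
             upper = 1 - exp(-exp(ll + z * se1)))
  } else {
    lp <- fit$transformed[["logit_psi"]]
    out <- c(lower = plogis(lp - z * se1), upper = plogis(lp + z * se1))
  }
  attr(out, "available") <- TRUE
  out
}

#' Serialize a fit to JSON
#'
#' @param fit An `occu_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  obj <- list(model = fit$model, estimates = as.list(fit$estimates),
              transformed = as.list(fit$transformed), se = as.list(fit$se),
              loglik = fit$loglik, converged = fit$converged,
              boundary = fit$boundary)
  if (!is.null(fit$K)) obj$K <- fit$K
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
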