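# Exact tests for site-level detection heterogeneity (binomial /
# zero-truncated binomial null) and for goodness of fit of each occupancy
# model's expected detections-per-site distribution.  Both are operationalised
# as a Monte Carlo exact multinomial goodness-of-fit test with the
# probability-ordering criterion: tables at least as improbable as the
# observed one, under the null, count as at least as extreme.

#' Binomial null for detections per occupied site
#'
#' MLE of the constant per-visit detection probability from occupied-site
#' counts (zeros included): `p_hat = sum(D) / (M * N)`.
#'
#' @param D Detections-per-site counts from occupied sites.
#' @param N Number of visits.
#' @return `p_hat`.
#' @export
fit_binomial_null <- function(D, N) {
  stopifnot(length(D) >= 1, all(D >= 0 & D <= N))
  sum(D) / (length(D) * N)
}

#' Zero-truncated binomial null for detected sites
#'
#' MLE of the per-visit detection probability when only sites with at least
#' one detection are observed: the root of
#' `mean(D) = N p / (1 - (1 - p)^N)` on `(0, 1]`.
#'
#' @param D Counts from sites with `D >= 1`.
#' @param N Number of visits.
#' @return `p_hat`.
#' @export
fit_ztb_null <- function(D, N) {
  stopifnot(all(D >= 1 & D <= N))
  m <- mean(D)
  if (m >= N) return(1)
  f <- function(p) N * p / (1 - (1 - p)^N) - m
  # truncated mean tends to 1 as p -> 0, so no root exists below mean(D) = 1
  if (m <= 1) return(1e-12)
  uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

# largest-remainder rounding of expected counts to integers preserving the
# total exactly; each category moves by < 1
integer_repair <- function(expected, total = round(sum(expected))) {
  fl <- floor(expected)
  rem <- expected - fl
  need <- total - sum(fl)
  if (need > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(need)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

#' Monte Carlo exact multinomial goodness-of-fit p-value
#'
#' Tests an observed table of category counts against expected counts by
#' sampling `n_mc` multinomial tables at the observed total from the expected
#' proportions; the p-value is the (add-one corrected) fraction of tables
#' whose multinomial probability is no larger than the observed table's.
#' A category with zero expected count but nonzero observed count gives the
#' observed table probability zero (strongest possible evidence). When the
#' p-value lands within two Monte Carlo SEs of `alpha`, the number of tables
#' is doubled (up to 8x) to stabilise the decision.
#'
#' @param observed Integer category counts.
#' @param expected Expected counts (same total as `observed`).
#' @param n_mc Number of Monte Carlo tables (`>= 1e4` recommended).
#' @param alpha Decision threshold used for adaptive refinement.
#' @return List: `p_value`, `mc_error` (binomial SE of `p_value`), `n_mc`.
#' @export
exact_gof_pvalue <- function(observed, expected, n_mc = 10000, alpha = 0.05) {
  stopifnot(length(observed) == length(expected), length(observed) >= 2,
            all(observed >= 0), all(expected >= 0))
  if (abs(sum(observed) - sum(expected)) > 0.5)
    stop("observed and expected totals differ")
  total <- sum(observed)
  prob <- expected / sum(expected)
  ltab <- function(x) {
    # log multinomial probability; 0 * log(0) treated as 0, x>0 on prob=0 -> -Inf
    if (any(x > 0 & prob == 0)) return(-Inf)
    keep <- x > 0
    lgamma(total + 1) - sum(lgamma(x + 1)) + sum(x[keep] * log(prob[keep]))
  }
  lobs <- ltab(observed)
  n_used <- 0L
  n_le <- 0L
  reps <- 0L
  repeat {
    tabs <- rmultinom(n_mc, total, prob)
    lp <- lgamma(total + 1) - colSums(lgamma(tabs + 1)) +
      colSums(tabs * ifelse(prob > 0, log(prob), 0))
    n_le <- n_le + sum(lp <= lobs + 1e-9)
    n_used <- n_used + n_mc
    p <- (1 + n_le) / (1 + n_used)
    mc_error <- sqrt(p * (1 - p) / n_used)
    reps <- reps + 1L
    if (abs(p - alpha) >= 2 * mc_error || reps >= 4L) break
  }
  list(p_value = p, mc_error = mc_error, n_mc = n_used)
}

# Two-sample Fisher construction: the observed counts and the
# integer-repaired expected counts form a 2 x K contingency table, tested
# with Fisher's exact test (Monte Carlo p-value).  Treating the expected
# table as a second sample makes this more conservative than the one-sample
# multinomial test in exact_gof_pvalue().
fisher_gof_pvalue <- function(observed, expected, n_mc = 10000) {
  keep <- observed + expected > 0
  tab <- rbind(observed[keep], expected[keep])
  if (ncol(tab) < 2) return(list(p_value = 1, mc_error = 0, n_mc = 0L))
  ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = n_mc)
  p <- ft$p.value
  list(p_value = p, mc_error = sqrt(p * (1 - p) / n_mc), n_mc = n_mc)
}

gof_dispatch <- function(method, observed, expected, n_mc, alpha) {
  if (method == "fisher") fisher_gof_pvalue(observed, expected, n_mc)
  else exact_gof_pvalue(observed, expected, n_mc, alpha)
}

new_test_result <- function(test, observed, expected, p, alpha = 0.05) {
  structure(list(test = test, observed = observed, expected = expected,
                 p_value = p$p_value, mc_error = p$mc_error, n_mc = p$n_mc,
                 alpha = alpha, flagged = p$p_value < alpha),
            class = "occuhet_test")
}

#' @export
print.occuhet_test <- function(x, ...) {
  cat(sprintf("%s: P = %.4f (MC error %.4f, %d tables) -> %s\n",
              x$test, x$p_value, x$mc_error, x$n_mc,
              if (x$flagged) sprintf("flagged at alpha = %g", x$alpha)
              else "not flagged"))
  invisible(x)
}

#' Exact test for site-level detection heterogeneity
#'
#' Tests whether the observed distribution of detections per occupied site
#' deviates from the distribution expected under a constant per-visit
#' detection probability. In `simulated` mode (truth flags available) the
#' null is a binomial fitted to all occupied sites, zeros included; in
#' `field` mode (truth unknown) it is a zero-truncated binomial fitted to
#' sites with at least one detection, over counts `1..N`. Expected counts
#' are integer-repaired by largest remainder and compared with the observed
#' counts by Fisher's exact test on the 2 x K observed-vs-expected table
#' (Monte Carlo p-value; `method = "multinomial"` substitutes the one-sample
#' exact multinomial test of [exact_gof_pvalue()]); heterogeneity is flagged
#' at `P < 0.05`.
#'
#' @param history A [detection_history()].
#' @param mode `"simulated"` or `"field"`.
#' @param n_mc Monte Carlo tables for the exact test.
#' @param alpha Decision threshold.
#' @param method `"fisher"` (two-sample observed-vs-expected table) or
#'   `"multinomial"` (one-sample exact multinomial).
#' @return An `occuhet_test` with observed/expected tables, `p_value`,
#'   `mc_error`, `n_mc` and the `flagged` decision.
#' @export
#' @examples
#' h <- simulate_beta_history(160, 20, psi = 1, seed = 1)
#' heterogeneity_test(h, "simulated")
heterogeneity_test <- function(history, mode = c("simulated", "field"),
                               n_mc = 10000, alpha = 0.05,
                               method = c("fisher", "multinomial")) {
  method <- match.arg(method)
  stopifnot(inherits(history, "detection_history"))
  mode <- match.arg(mode)
  N <- n_visits(history)
  if (N < 2) stop("heterogeneity test undefined for single-visit histories")
  D <- site_counts(history)
  if (mode == "simulated") {
    if (is.null(history$z))
      stop("simulated mode requires occupancy truth flags `z`")
    D <- D[history$z]
    if (length(D) < 2) stop("need at least 2 occupied sites")
    p_hat <- fit_binomial_null(D, N)
    support <- 0:N
    pm <- dbinom(support, N, p_hat)
    obs <- tabulate(D + 1L, nbins = N + 1L)
  } else {
    D <- D[D >= 1]
    if (length(D) < 2) stop("need at least 2 sites with detections")
    p_hat <- fit_ztb_null(D, N)
    support <- 1:N
    pm <- dbinom(support, N, p_hat) / (1 - (1 - p_hat)^N)
    obs <- tabulate(D, nbins = N)
  }
  expected <- integer_repair(length(D) * pm / sum(pm), length(D))
  res <- new_test_result(sprintf("detection heterogeneity (%s mode)", mode),
                         stats::setNames(obs, support),
                         stats::setNames(expected, support),
                         gof_dispatch(method, obs, expected, n_mc, alpha),
                         alpha)
  res$p_hat_null <- p_hat
  res
}

#' Exact goodness-of-fit test for a fitted occupancy model
#'
#' Tests whether the observed distribution of detections per site (all `M`
#' sites, counts `0..N`) deviates from the distribution expected under the
#' fitted model ([expected_distribution()]); the model fails the test at
#' `P < 0.05`.
#'
#' @param fit An `occu_fit`.
#' @param history The [detection_history()] the model was fitted to.
#' @param n_mc Monte Carlo tables for the exact test.
#' @param alpha Decision threshold.
#' @param method `"fisher"` (two-sample observed-vs-expected table) or
#'   `"multinomial"` (one-sample exact multinomial).
#' @return An `occuhet_test`.
#' @export
gof_test <- function(fit, history, n_mc = 10000, alpha = 0.05,
                     method = c("fisher", "multinomial")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "occu_fit"), inherits(history, "detection_history"))
  D <- site_counts(history)
  N <- n_visits(history)
  M <- length(D)
  obs <- tabulate(D + 1L, nbins = N + 1L)
  expected <- integer_repair(expected_distribution(fit, M, N), M)
  new_test_result(sprintf("goodness of fit (%s model)", fit$model),
                  stats::setNames(obs, 0:N),
                  stats::setNames(expected, 0:N),
                  gof_dispatch(method, obs, expected, n_mc, alpha), alpha)
}

#' Serialize a test result to JSON
#' @param result An `occuhet_test`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_test_result <- function(result, path) {
  jsonlite::write_json(
    list(test = result$test, observed = as.list(result$observed),
         expected = as.list(result$expected), p_value = result$p_value,
         mc_error = result$mc_error, n_mc = result$n_mc,
         alpha = result$alpha, flagged = result$flagged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
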