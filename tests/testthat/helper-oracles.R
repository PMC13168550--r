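# Shared oracles, independent of the implementation paths they check.

# per-visit detection probability for stationary birds at distances d:
# cues are a thinned Poisson process, so P(detect) = 1 - exp(-nu*t*sum g(d))
stationary_detect_prob <- function(d, edr = 60, cue_rate = 0.25,
                                   duration = 10) {
  1 - exp(-cue_rate * duration * sum(exp(-(d / edr)^2)))
}

# exact multinomial GOF p-value by full enumeration (probability ordering)
enumerate_gof_pvalue <- function(observed, prob) {
  total <- sum(observed)
  k <- length(prob)
  grid <- expand.grid(rep(list(0:total), k - 1))
  tabs <- cbind(grid, total - rowSums(grid))
  tabs <- tabs[tabs[, k] >= 0, , drop = FALSE]
  lp <- apply(tabs, 1, function(x) dmultinom(x, prob = prob, log = TRUE))
  lobs <- dmultinom(observed, prob = prob, log = TRUE)
  sum(exp(lp[lp <= lobs + 1e-9]))
}

# direct fast path to the compiled visit simulator
visits_cpp <- function(nest_x, nest_y, sd, n_visits, edr = 60, rate = 1,
                       cue = 0.25, dur = 10, ctr = 750) {
  occuhet:::simulate_visits_cpp(nest_x, nest_y, sd, rate, cue, dur, edr,
                                as.integer(n_visits), ctr, ctr)
}
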