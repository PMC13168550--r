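# Experiment harness: visit/site subsampling, accuracy metrics, diagnosis
# timing, and the scenario grid crossing density x territory size x occupancy.

#' Shorten a detection history to T visits
#'
#' Simulated mode keeps the first `T` columns. Field mode first shuffles the
#' visit order independently within each site (removing date structure), then
#' keeps the first `T` of the shuffled visits. Truth flags are preserved.
#'
#' @param history A [detection_history()].
#' @param T Number of visits to keep, `2 <= T <= N`.
#' @param mode `"simulated"` or `"field"`.
#' @return A [detection_history()] with `T` columns.
#' @export
subsample_visits <- function(history, T, mode = c("simulated", "field")) {
  stopifnot(inherits(history, "detection_history"))
  mode <- match.arg(mode)
  N <- n_visits(history)
  if (T < 2 || T > N) stop("`T` must lie in [2, N]")
  y <- history$y
  if (mode == "field")
    y <- t(apply(y, 1, function(row) row[sample.int(N)]))
  detection_history(y[, seq_len(T), drop = FALSE], history$z, history$config)
}

#' Reduce the number of occupied sites in a history
#'
#' Keeps a uniform random subset of `target` occupied rows and pads with
#' all-zero unoccupied rows so the total number of sites is unchanged.
#' Mirrors deriving the 20%- and 50%-occupancy datasets from a single
#' 160-occupied-site simulation.
#'
#' @param history A [detection_history()] with truth flags.
#' @param target Number of occupied sites to keep.
#' @return A [detection_history()].
#' @export
subsample_occupied_sites <- function(history, target) {
  stopifnot(inherits(history, "detection_history"), !is.null(history$z))
  occ <- which(history$z)
  if (target > length(occ)) stop("`target` exceeds available occupied sites")
  keep <- if (target == length(occ)) occ else sort(sample(occ, target))
  M <- nrow(history$y)
  y <- rbind(history$y[keep, , drop = FALSE],
             matrix(0L, M - target, n_visits(history)))
  detection_history(y, c(rep(TRUE, target), rep(FALSE, M - target)),
                    history$config)
}

#' Naive occupancy of a history
#'
#' Fraction of sites with at least one detection in the data at hand.
#'
#' @param history A [detection_history()].
#' @return Proportion in `[0, 1]`.
#' @export
naive_occupancy <- function(history) {
  stopifnot(inherits(history, "detection_history"))
  mean(rowSums(history$y) >= 1)
}

#' Sample-at-hand occupancy
#'
#' Naive occupancy of the full (all-visit) history: the maximum naive
#' occupancy attainable from any visit subset, and a known lower bound on
#' true occupancy.
#'
#' @param history_full The full [detection_history()].
#' @return Proportion in `[0, 1]`.
#' @export
sample_at_hand <- function(history_full) naive_occupancy(history_full)

#' Occupancy estimation error in percentage points
#'
#' `100 * (psi_hat - true fraction occupied)`, the difference between
#' model-estimated occupancy and the realized proportion of occupied sites.
#'
#' @param fit An `occu_fit`.
#' @param history A [detection_history()] with truth flags.
#' @return Error in percentage points.
#' @export
occupancy_error <- function(fit, history) {
  stopifnot(inherits(fit, "occu_fit"), inherits(history, "detection_history"))
  if (is.null(history$z)) stop("occupancy truth flags required")
  100 * (fit$estimates[["psi"]] - mean(history$z))
}

#' Visits needed to diagnose a problem
#'
#' Applies `test_fun` to the history shortened to each `T` in `T_grid`
#' (ascending) and returns the smallest `T` at which the test flags
#' (`p < alpha`), or `NA` if it never does.
#'
#' @param history A [detection_history()].
#' @param test_fun Function of a history returning an `occuhet_test` (e.g.
#'   `function(h) heterogeneity_test(h, "simulated")`).
#' @param T_grid Ascending visit counts to evaluate.
#' @param mode Passed to [subsample_visits()].
#' @return The first flagged `T`, or `NA_integer_`.
#' @export
visits_to_diagnose <- function(history, test_fun, T_grid = 2:n_visits(history),
                               mode = "simulated") {
  for (T in sort(T_grid)) {
    res <- test_fun(subsample_visits(history, T, mode))
    if (isTRUE(res$flagged)) return(as.integer(T))
  }
  NA_integer_
}

#' Configuration of a scenario grid
#'
#' Crosses density levels (optionally plus an exactly-one-bird level),
#' movement SDs and occupancy levels; each combination is replicated
#' `n_reps` times. Occupied sites are simulated once per (density, movement
#' SD, replicate) at the highest occupancy level and subsampled to the lower
#' levels, mirroring how the simulated datasets share occupied sites across
#' occupancy levels.
#'
#' @param densities Bird densities (ha^-1) at occupied sites.
#' @param include_exactly_one Add the exactly-one-bird density level?
#' @param movement_sds Per-axis movement SDs (m).
#' @param psis Occupancy levels (proportions of `n_sites`).
#' @param edr Effective detection radius (m).
#' @param n_reps Replicates per scenario.
#' @param n_sites,n_visits History dimensions.
#' @param T_values Visit lengths at which models are fitted and tested.
#' @param n_mc Monte Carlo tables per exact test.
#' @param seed Base seed; every dataset's seed is derived from it.
#' @return A `grid_config` list.
#' @export
grid_config <- function(densities = c(0.1, 0.25, 0.5, 1, 2),
                        include_exactly_one = TRUE,
                        movement_sds = c(0, 10, 25, 50, 100),
                        psis = c(0.2, 0.5, 0.8), edr = 60, n_reps = 10,
                        n_sites = 200, n_visits = 20,
                        T_values = c(2, n_visits), n_mc = 10000, seed = 1) {
  stopifnot(n_reps >= 1, all(T_values >= 2), all(T_values <= n_visits))
  structure(list(densities = densities,
                 include_exactly_one = include_exactly_one,
                 movement_sds = movement_sds, psis = sort(psis, TRUE),
                 edr = edr, n_reps = as.integer(n_reps),
                 n_sites = as.integer(n_sites),
                 n_visits = as.integer(n_visits),
                 T_values = sort(unique(as.integer(T_values))),
                 n_mc = n_mc, seed = as.integer(seed)),
            class = "grid_config")
}

grid_density_levels <- function(grid) {
  lv <- as.character(grid$densities)
  if (grid$include_exactly_one) lv <- c(lv, "exactly_one")
  lv
}

# fit one model defensively; failures are recorded, never fatal
fit_one <- function(model, history, K = 60) {
  fitter <- switch(model, basic = fit_basic, zibb = fit_zibb,
                   rn = function(h) fit_rn(h, K = K))
  tryCatch(suppressWarnings(fitter(history)), error = function(e) NULL)
}

#' Run a scenario grid
#'
#' For every (density, movement SD, replicate): simulate the occupied sites
#' at the highest occupancy level, derive the lower-occupancy datasets by
#' subsampling occupied sites, then for each occupancy level and visit length
#' `T` fit the basic, RN and ZIBB models and record estimates, errors, CIs,
#' boundary flags and goodness-of-fit p-values; the detection-heterogeneity
#' test runs once per dataset on the full history. Fully deterministic given
#' `grid$seed`; individual fit failures are recorded as `NA` rows. Optionally
#' writes one JSON record per dataset to `out_dir` and skips datasets whose
#' record already exists, making long runs resumable.
#'
#' @param grid A [grid_config()].
#' @param out_dir Optional directory for per-dataset JSON records.
#' @param progress Print one line per simulated block?
#' @return A `grid_result`: list with `fits` (one row per dataset x model x
#'   T) and `tests` (one row per dataset) data.frames. Summarise with
#'   [summarize_grid()].
#' @export
run_grid <- function(grid, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(grid, "grid_config"))
  dens_levels <- grid_density_levels(grid)
  psi_max <- max(grid$psis)
  fit_rows <- list()
  test_rows <- list()
  unit <- 0L
  for (dl in dens_levels) for (sdm in grid$movement_sds)
    for (rep_i in seq_len(grid$n_reps)) {
      unit <- unit + 1L
      key <- sprintf("d%s_sd%g_rep%d", dl, sdm, rep_i)
      rec_path <- if (!is.null(out_dir))
        file.path(out_dir, paste0(key, ".json")) else NULL
      if (!is.null(rec_path) && file.exists(rec_path)) {
        rec <- jsonlite::read_json(rec_path, simplifyVector = TRUE)
        fit_rows[[key]] <- rec$fits
        test_rows[[key]] <- rec$tests
        next
      }
      exactly_one <- identical(dl, "exactly_one")
      cfg <- scenario_config(density = if (exactly_one) 0 else as.numeric(dl),
                             exactly_one = exactly_one, movement_sd = sdm,
                             edr = grid$edr, psi = psi_max,
                             n_sites = grid$n_sites,
                             n_visits = grid$n_visits,
                             seed = derive_seed(grid$seed, unit))
      if (progress)
        cat(sprintf("[%d] simulating %s\n", unit, key))
      full <- simulate_scenario(cfg)
      uf <- list()
      ut <- list()
      for (psi in grid$psis) {
        set.seed(derive_seed(cfg$seed, 1000L + round(psi * 100)))
        hist_psi <- if (psi == psi_max) full else
          subsample_occupied_sites(full, round(psi * grid$n_sites))
        het <- heterogeneity_test(hist_psi, "simulated", grid$n_mc)
        ut[[length(ut) + 1L]] <- data.frame(
          density = dl, movement_sd = sdm, psi = psi, rep = rep_i,
          het_p = het$p_value, het_flagged = het$flagged,
          stringsAsFactors = FALSE)
        for (T in grid$T_values) {
          h_T <- subsample_visits(hist_psi, T, "simulated")
          for (model in c("basic", "rn", "zibb")) {
            fit <- fit_one(model, h_T)
            row <- data.frame(
              density = dl, movement_sd = sdm, psi = psi, rep = rep_i,
              model = model, T = T, psi_hat = NA_real_, error = NA_real_,
              rel_error = NA_real_, naive = naive_occupancy(h_T),
              lower = NA_real_, upper = NA_real_, covered = NA,
              ci_width = NA_real_, boundary = NA, converged = FALSE,
              gof_p = NA_real_, gof_flagged = NA, stringsAsFactors = FALSE)
            if (!is.null(fit)) {
              ci <- wald_ci(fit)
              truth <- mean(hist_psi$z)
              row$psi_hat <- fit$estimates[["psi"]]
              row$error <- occupancy_error(fit, hist_psi)
              row$rel_error <- row$error / truth
              row$lower <- ci[["lower"]]; row$upper <- ci[["upper"]]
              row$covered <- if (attr(ci, "available"))
                ci[["lower"]] <= truth && truth <= ci[["upper"]] else NA
              row$ci_width <- ci[["upper"]] - ci[["lower"]]
              row$boundary <- fit$boundary
              row$converged <- fit$converged
              gof <- gof_test(fit, h_T, grid$n_mc)
              row$gof_p <- gof$p_value
              row$gof_flagged <- gof$flagged
            }
            uf[[length(uf) + 1L]] <- row
          }
        }
      }
      fit_rows[[key]] <- do.call(rbind, uf)
      test_rows[[key]] <- do.call(rbind, ut)
      if (!is.null(rec_path)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(list(fits = fit_rows[[key]],
                                  tests = test_rows[[key]]),
                             rec_path, digits = NA)
      }
    }
  structure(list(fits = do.call(rbind, c(fit_rows, make.row.names = FALSE)),
                 tests = do.call(rbind, c(test_rows, make.row.names = FALSE)),
                 grid = grid),
            class = "grid_result")
}

#' Summarise a grid run
#'
#' Aggregates per-dataset records into the accuracy metrics: mean and SD of
#' occupancy error, both in percentage points and relative to the true
#' fraction occupied (all fits, and excluding boundary fits), coverage of the
#' 95% CI (where available), mean CI width, boundary rate and
#' goodness-of-fit failure rate per (model, T); plus the
#' detection-heterogeneity flag rate per occupancy level.
#'
#' @param result A `grid_result` from [run_grid()].
#' @return List of data.frames `by_model_T` and `het_by_psi`.
#' @export
summarize_grid <- function(result) {
  stopifnot(inherits(result, "grid_result"))
  f <- result$fits
  key <- interaction(f$model, f$T, drop = TRUE)
  by_model_T <- do.call(rbind, lapply(split(f, key), function(g) {
    ok <- !is.na(g$error)
    nb <- ok & !ifelse(is.na(g$boundary), FALSE, g$boundary)
    data.frame(model = g$model[1], T = g$T[1],
               mean_error = mean(g$error[ok]), sd_error = sd(g$error[ok]),
               mean_rel_error = mean(g$rel_error[ok]),
               sd_rel_error = sd(g$rel_error[ok]),
               mean_error_nonboundary = mean(g$error[nb]),
               mean_rel_error_nonboundary = mean(g$rel_error[nb]),
               coverage = mean(g$covered[ok], na.rm = TRUE),
               mean_ci_width = mean(g$ci_width[ok], na.rm = TRUE),
               boundary_rate = mean(g$boundary[ok]),
               gof_failure_rate = mean(g$gof_flagged[ok]),
               fit_failure_rate = mean(!ok),
               n = sum(ok), stringsAsFactors = FALSE)
  }))
  rownames(by_model_T) <- NULL
  t <- result$tests
  het_by_psi <- aggregate(het_flagged ~ psi, data = t, FUN = mean)
  names(het_by_psi)[2] <- "het_flag_rate"
  list(by_model_T = by_model_T, het_by_psi = het_by_psi)
}

#' Write a grid summary to CSV
#' @param result A `grid_result`.
#' @param path Output CSV path (per model x T summary).
#' @return `path`, invisibly.
#' @export
write_grid_summary <- function(result, path) {
  write.csv(summarize_grid(result)$by_model_T, path, row.names = FALSE)
  invisible(path)
}
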