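# File formats: detection histories as CSV (site_id, occupied_truth,
# visit_1..visit_N) with a JSON sidecar carrying the configuration and seed;
# scenario configurations as YAML.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a detection history to CSV
#'
#' Columns `site_id`, `occupied_truth` (0/1, omitted when truth is absent)
#' and `visit_1..visit_N`; a JSON sidecar (`<path>.json`) stores the
#' configuration, seed and package version for provenance.
#'
#' @param history A [detection_history()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  stopifnot(inherits(history, "detection_history"))
  y <- history$y
  df <- data.frame(site_id = seq_len(nrow(y)))
  if (!is.null(history$z)) df$occupied_truth <- as.integer(history$z)
  colnames(y) <- paste0("visit_", seq_len(ncol(y)))
  df <- cbind(df, as.data.frame(y))
  write.csv(df, path, row.names = FALSE)
  cfg <- history$config
  meta <- list(config = if (inherits(cfg, "scenario_config"))
                 unclass(cfg) else cfg,
               seed = if (!is.null(cfg)) cfg$seed,
               package_version = as.character(utils::packageVersion("occuhet")))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a detection history from CSV
#'
#' Validates the schema written by [write_history()]: a rectangular
#' `visit_1..visit_N` block of 0/1 values (blank = missing), unique
#' `site_id`s, and an `occupied_truth` column that is either fully present
#' or absent. Histories containing missing visits are readable but are
#' rejected by the model-fitting functions, which assume complete N-visit
#' histories.
#'
#' @param path CSV path.
#' @return A [detection_history()]; metadata from the JSON sidecar, if
#'   present, is attached as `config`.
#' @export
read_history <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE)
  vcols <- grep("^visit_[0-9]+$", names(df), value = TRUE)
  if (length(vcols) == 0) stop("no visit_1..visit_N columns found")
  vcols <- vcols[order(as.integer(sub("visit_", "", vcols)))]
  if (!"site_id" %in% names(df)) stop("missing `site_id` column")
  if (anyDuplicated(df$site_id))
    stop("duplicate site_id: ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  y <- as.matrix(df[, vcols, drop = FALSE])
  bad <- which(!(is.na(y) | y %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-binary value in row %d, column %s",
                 bad[1, 1], vcols[bad[1, 2]]))
  if (anyNA(y))
    stop(paste("history contains missing visits; storage allows them but the",
               "occupancy models assume complete N-visit histories"))
  z <- NULL
  if ("occupied_truth" %in% names(df)) {
    zt <- df$occupied_truth
    if (anyNA(zt))
      stop("`occupied_truth` must be fully present or fully absent")
    if (!all(zt %in% c(0, 1))) stop("`occupied_truth` must be 0/1")
    z <- as.logical(zt)
  }
  cfg <- NULL
  if (file.exists(sidecar_path(path)))
    cfg <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)$config
  detection_history(y, z, cfg)
}

#' Read a scenario configuration from YAML
#'
#' Accepts any subset of the [scenario_config()] arguments; the rest take
#' their defaults.
#'
#' @param path YAML file.
#' @return A [scenario_config()].
#' @export
read_scenario_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown scenario fields: ", paste(unknown, collapse = ", "))
  do.call(scenario_config, vals)
}

#' Write a scenario configuration to YAML
#' @param config A [scenario_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null, TRUE)],
                   path)
  invisible(path)
}
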