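#' Read and write long-format rating tables
#'
#' CSV with header `examinee,task,rater,score`, 1-based ids. Missing triples
#' are written as absent rows; on read, rows with `score = -1` (an accepted
#' missing-data sentinel) are dropped. Scores outside `1..K` are rejected.
#'
#' @param data Rating tibble.
#' @param path File path.
#' @param K Number of categories for validation on read (optional).
#'
#' @return `write_ratings()` returns `path` invisibly; `read_ratings()` a
#'   tibble with integer columns `examinee`, `task`, `rater`, `score`.
#' @export
write_ratings <- function(data, path) {
  readr::write_csv(data[c("examinee", "task", "rater", "score")], path)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path, K = NULL) {
  out <- readr::read_csv(path, col_types = readr::cols(
    examinee = readr::col_integer(), task = readr::col_integer(),
    rater = readr::col_integer(), score = readr::col_integer()))
  bad <- out$score < 1L & out$score != -1L
  if (!is.null(K)) bad <- bad | out$score > K
  if (any(bad)) {
    # +1 for the header: report the file line, not the data row
    abort(sprintf("Score out of range at line %d of %s.",
                  which(bad)[1] + 1L, path),
          class = "facetlink_parse_error")
  }
  out <- out[out$score != -1L, ]
  if (any(duplicated(out[c("examinee", "task", "rater")]))) {
    abort("Duplicate (examinee, task, rater) triple in ratings file.",
          class = "facetlink_parse_error")
  }
  out
}

#' Read and write MFRM parameter files
#'
#' JSON with keys `theta`, `beta`, `gamma`, `d` and `K`. The category
#' constraints (`d[1] = 0`, `sum(d[2..K]) = 0`) are enforced on read, so a
#' hand-edited file that violates them is rejected.
#'
#' @param params An [mfrm_params()] object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()` an
#'   `mfrm_params` object.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(
    list(theta = params$theta, beta = params$beta, gamma = params$gamma,
         d = params$d, K = params$K),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("theta", "beta", "gamma", "d")
  if (!all(need %in% names(raw))) {
    abort("Parameter file must contain theta, beta, gamma, d.",
          class = "facetlink_parse_error")
  }
  d <- as.numeric(raw$d)
  # tolerate write/read float noise, then re-pin the constraint exactly
  if (abs(d[1]) > 1e-9 || abs(sum(d[-1])) > 1e-9) {
    abort("Category parameters violate d[1] = 0 / sum-to-zero constraints.",
          class = "facetlink_parse_error")
  }
  d[1] <- 0
  d[length(d)] <- -sum(d[-c(1, length(d))])
  mfrm_params(raw$theta, raw$beta, raw$gamma, d)
}

#' Export a rater assignment design
#'
#' CSV of the assigned `examinee,task,rater` triples (1-based).
#'
#' @param design A [build_design()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_csv(tibble::as_tibble(design)[c("examinee", "task", "rater")],
                   path)
  invisible(path)
}

#' Write a grid report to CSV
#'
#' @param report A [run_grid()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_grid_report <- function(report, path) {
  readr::write_csv(tibble::as_tibble(report), path)
  invisible(path)
}

#' Load an experiment configuration from YAML
#'
#' Reads a YAML experiment description and returns a validated
#' [experiment_config()] with defaults filled in (`K = 5`, 30 replications,
#' standard-normal base distributions, complete design, drift off, RMSE over
#' all free parameters). Unknown keys at any level are rejected by name,
#' so typos cannot silently fall back to defaults.
#'
#' Schema (all blocks optional except `J`, `I`, `R`):
#' ```yaml
#' J: 100
#' I: 10
#' R: 10
#' K: 5
#' seed: 1
#' replications: 30
#' new: {scenario: 1}            # or per-class {theta: {mean: -0.5, sd: 1}, ...}
#' base: {theta: {mean: 0, sd: 1}}
#' grid: {C_R: [1,2,3,4,5], C_I: [1,2,3,4,5]}
#' design: {type: rater_set, N_R: 2}
#' drift: {enabled: true, sd_task: 0.05, sd_rater: 0.10}
#' error: {index: rmse, scope: all_free}
#' mcmc: {iterations: 5000, burn_in: 2000, thinning: 2, chains: 1}
#' ```
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config`.
#' @examples
#' cfg <- load_config(system.file("extdata", "example-experiment.yaml",
#'                                package = "facetlink"))
#' cfg
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("J", "I", "R", "K", "seed", "replications", "base", "new",
             "grid", "design", "drift", "error", "mcmc")
  check_keys(raw, known, "top level")
  for (fld in c("J", "I", "R")) {
    if (is.null(raw[[fld]])) {
      abort(sprintf("Config key '%s' is required.", fld),
            class = "facetlink_config_error")
    }
  }
  base_spec <- yaml_spec(raw$base, "base")
  new_spec <- yaml_spec(raw$new, "new")
  grid <- raw$grid %||% list()
  check_keys(grid, c("C_R", "C_I"), "grid")
  design <- raw$design %||% list(type = "complete")
  check_keys(design, c("type", "N_R"), "design")
  drift <- raw$drift %||% list()
  check_keys(drift, c("enabled", "sd_task", "sd_rater"), "drift")
  err <- raw$error %||% list()
  check_keys(err, c("index", "scope"), "error")
  mc <- raw$mcmc %||% list()
  check_keys(mc, c("iterations", "burn_in", "thinning", "chains"), "mcmc")
  experiment_config(
    J = raw$J, I = raw$I, R = raw$R, K = raw$K %||% 5,
    base_spec = base_spec, new_spec = new_spec,
    C_R = unlist(grid$C_R) %||% 1:5, C_I = unlist(grid$C_I) %||% 1:5,
    replications = raw$replications %||% 30,
    design = design$type %||% "complete", N_R = design$N_R,
    drift = drift$enabled %||% FALSE,
    drift_sd_task = drift$sd_task %||% 0.05,
    drift_sd_rater = drift$sd_rater %||% 0.10,
    error_index = unlist(err$index) %||% "rmse",
    error_scope = unlist(err$scope) %||% "all_free",
    mcmc = mcmc_config(iterations = mc$iterations %||% 5000,
                       burn_in = mc$burn_in %||% 2000,
                       thinning = mc$thinning %||% 2,
                       chains = mc$chains %||% 1),
    seed = raw$seed %||% 1L
  )
}

check_keys <- function(lst, known, where) {
  extra <- setdiff(names(lst), known)
  if (length(extra)) {
    abort(sprintf("Unknown config key '%s' at %s.", extra[1], where),
          class = "facetlink_config_error")
  }
  invisible(lst)
}

yaml_spec <- function(blk, where) {
  if (is.null(blk)) {
    return(if (where == "new") scenario_spec(1) else distribution_spec())
  }
  if (!is.null(blk$scenario)) {
    check_keys(blk, "scenario", where)
    return(scenario_spec(blk$scenario))
  }
  check_keys(blk, c("theta", "beta", "gamma", "d"), where)
  args <- list()
  for (cls in c("theta", "beta", "gamma", "d")) {
    sub <- blk[[cls]]
    if (is.null(sub)) next
    check_keys(sub, c("mean", "sd"), paste(where, cls))
    if (!is.null(sub$mean)) args[[paste0(cls, "_mean")]] <- sub$mean
    if (!is.null(sub$sd)) args[[paste0(cls, "_sd")]] <- sub$sd
  }
  do.call(distribution_spec, args)
}
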