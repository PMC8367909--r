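#' Configure a linking-accuracy experiment
#'
#' Bundles everything one simulation study needs: test dimensions, the
#' generating distributions of the base and new tests, the grid of
#' commonality counts, the rating design, optional anchor drift, the error
#' index, the sampler settings and the master seed.
#'
#' @param J,I,R Numbers of examinees, tasks, raters (identical for both
#'   tests).
#' @param K Number of rating categories (default 5).
#' @param base_spec Generating distributions for the base test; default all
#'   classes standard normal, which is also the estimation prior.
#' @param new_spec Generating distributions for the new test; see
#'   [scenario_spec()] for the canonical shift conditions.
#' @param C_R,C_I Integer vectors: the grid of common-rater and common-task
#'   counts to evaluate.
#' @param replications Replications per cell (>= 2; the threshold needs a
#'   sample SD). 30 matches the full study conditions; smaller values give
#'   desk-scale runs.
#' @param design `"complete"` (every rater rates everything) or
#'   `"rater_set"` (missing by design; requires `N_R`).
#' @param N_R Raters per evaluation target under the rater-set design.
#' @param drift Logical: add zero-mean fluctuations to about half of the
#'   common raters/tasks before sampling (see [inject_drift()]).
#' @param drift_sd_task,drift_sd_rater Fluctuation SDs.
#' @param error_index Character vector among `"rmse"`, `"mae"`,
#'   `"abs_mean_bias"`.
#' @param error_scope Character vector among `"all_free"`, `"ability"`,
#'   `"task"`, `"rater"`, `"category"`.
#' @param mcmc An [mcmc_config()].
#' @param seed Master seed; all stage seeds derive from it via
#'   [derive_seed()].
#'
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(J, I, R, K = 5,
                              base_spec = distribution_spec(),
                              new_spec = scenario_spec(1),
                              C_R = 1:5, C_I = 1:5,
                              replications = 30,
                              design = c("complete", "rater_set"),
                              N_R = NULL,
                              drift = FALSE,
                              drift_sd_task = 0.05, drift_sd_rater = 0.10,
                              error_index = "rmse",
                              error_scope = "all_free",
                              mcmc = mcmc_config(),
                              seed = 1L) {
  design <- match.arg(design)
  if (replications < 2) {
    abort("replications must be >= 2 (the threshold needs a sample SD).",
          class = "facetlink_config_error")
  }
  if (any(C_R < 0) || any(C_R > R) || any(C_I < 0) || any(C_I > I)) {
    abort("Grid values C_R/C_I must lie within the rater/task counts.",
          class = "facetlink_config_error")
  }
  if (design == "rater_set") {
    if (is.null(N_R)) abort("rater_set design requires N_R.",
                            class = "facetlink_invalid_design")
    check_design_args(R, N_R)
  }
  bad <- setdiff(error_index, c("rmse", "mae", "abs_mean_bias"))
  if (length(bad)) abort(paste("Unknown error index:", bad),
                         class = "facetlink_config_error")
  bad <- setdiff(error_scope, c("all_free", "ability", "task", "rater", "category"))
  if (length(bad)) abort(paste("Unknown error scope:", bad),
                         class = "facetlink_config_error")
  structure(list(J = J, I = I, R = R, K = K,
                 base_spec = base_spec, new_spec = new_spec,
                 C_R = as.integer(C_R), C_I = as.integer(C_I),
                 replications = as.integer(replications),
                 design = design, N_R = if (is.null(N_R)) NULL else as.integer(N_R),
                 drift = isTRUE(drift),
                 drift_sd_task = drift_sd_task, drift_sd_rater = drift_sd_rater,
                 error_index = error_index, error_scope = error_scope,
                 mcmc = mcmc, seed = as.integer(seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> J=%d I=%d R=%d K=%d | %s%s | %d reps | seed %d\n",
              x$J, x$I, x$R, x$K, x$design,
              if (x$design == "rater_set") sprintf(" (N_R=%d, %.0f%% missing)",
                                                   x$N_R, missing_rate(x$R, x$N_R)) else "",
              x$replications, x$seed))
  cat(sprintf("  grid: C_R in {%s}, C_I in {%s}; drift %s; index %s over %s\n",
              paste(x$C_R, collapse = ","), paste(x$C_I, collapse = ","),
              if (x$drift) "on" else "off",
              paste(x$error_index, collapse = "/"),
              paste(x$error_scope, collapse = "/")))
  invisible(x)
}

#' Linking error between estimated and true parameter sets
#'
#' Deviations `estimate - truth` are taken over the *free* parameters of the
#' requested scope — anchored gamma/beta entries are excluded by default,
#' since their deviation is identically zero and would deflate the index
#' (set `include_anchored = TRUE` for sensitivity checks). The category
#' scope covers `d[2..K]` (`d[1]` is structural).
#'
#' @param est,truth [mfrm_params()] objects of matching dimensions.
#' @param index `"rmse"` (root mean squared deviation), `"mae"` (mean
#'   absolute deviation) or `"abs_mean_bias"` (absolute value of the mean
#'   deviation).
#' @param scope `"all_free"`, `"ability"`, `"task"`, `"rater"` or
#'   `"category"`.
#' @param mask A [fixed_mask()] naming the anchored entries, or `NULL`.
#' @param include_anchored Include anchored entries despite the mask.
#'
#' @return Scalar error value.
#' @examples
#' p <- mfrm_params(c(0, 1), 0.2, c(0, 0.3), d = c(0, -0.5, 0.5))
#' q <- p; q$theta <- p$theta + 0.1
#' compute_error(q, p, scope = "ability") # 0.1
#' @export
compute_error <- function(est, truth, index = c("rmse", "mae", "abs_mean_bias"),
                          scope = c("all_free", "ability", "task", "rater",
                                    "category"),
                          mask = NULL, include_anchored = FALSE) {
  index <- match.arg(index)
  scope <- match.arg(scope)
  stopifnot(est$J == truth$J, est$I == truth$I, est$R == truth$R,
            est$K == truth$K)
  fixed_b <- if (!mask_is_empty(mask) && !include_anchored) mask$beta_idx else integer(0)
  fixed_g <- if (!mask_is_empty(mask) && !include_anchored) mask$gamma_idx else integer(0)
  dev_theta <- est$theta - truth$theta
  dev_beta <- (est$beta - truth$beta)[setdiff(seq_len(est$I), fixed_b)]
  dev_gamma <- (est$gamma - truth$gamma)[setdiff(seq_len(est$R), fixed_g)]
  dev_d <- (est$d - truth$d)[-1]
  dev <- switch(scope,
    all_free = c(dev_theta, dev_beta, dev_gamma, dev_d),
    ability = dev_theta,
    task = dev_beta,
    rater = dev_gamma,
    category = dev_d
  )
  if (length(dev) == 0L) {
    abort("Requested scope contains no free parameters.",
          class = "facetlink_invalid_scope")
  }
  switch(index,
    rmse = sqrt(mean(dev^2)),
    mae = mean(abs(dev)),
    abs_mean_bias = abs(mean(dev))
  )
}

#' Run one replication of the linking simulation
#'
#' Executes the six-step procedure for one cell and replication: generate
#' base-test truth (all classes standard normal), generate new-test truth
#' from the configured shifted distributions, embed `C_R` common raters and
#' `C_I` common tasks, optionally build the rater-set design and inject
#' anchor drift, sample the new test's ratings, estimate its parameters by
#' EAP with the anchors fixed at the base-test values, and compute every
#' configured error index/scope against the (undrifted) truth.
#'
#' Each stage draws from its own seed derived via [derive_seed()], so a
#' replication is a pure function of `(config, C_R, C_I, rep, calibration)`
#' and stages can be replayed in isolation. Calibration replications (used
#' for the threshold) regenerate the new test from the *base* distributions
#' and never apply drift.
#'
#' @param config An [experiment_config()].
#' @param C_R,C_I Commonality counts for this cell.
#' @param rep Replication number.
#' @param calibration Logical; `TRUE` for threshold-calibration runs.
#'
#' @return A tibble with columns `index`, `scope`, `error`.
#' @export
run_replication <- function(config, C_R, C_I, rep, calibration = FALSE) {
  tag <- if (calibration) "cal" else "run"
  stage_seed <- function(stage) {
    derive_seed(config$seed, C_R, C_I, rep, paste0(tag, "-", stage))
  }
  new_spec <- if (calibration) config$base_spec else config$new_spec

  set.seed(stage_seed("base"))
  base <- generate_parameters(config$J, config$I, config$R, config$K,
                              config$base_spec)
  set.seed(stage_seed("new"))
  new <- generate_parameters(config$J, config$I, config$R, config$K, new_spec)
  set.seed(stage_seed("embed"))
  emb <- embed_common(base, new, C_R, C_I)

  design <- if (config$design == "rater_set") {
    build_design(config$J, config$I, config$R, config$N_R)
  } else NULL

  samp_params <- emb$params
  if (config$drift && !calibration) {
    set.seed(stage_seed("drift"))
    samp_params <- inject_drift(emb$params, emb$layout,
                                sd_task = config$drift_sd_task,
                                sd_rater = config$drift_sd_rater)
  }
  set.seed(stage_seed("sample"))
  dat <- sample_dataset(samp_params, design)

  mask <- fixed_mask(emb$layout)
  cfg <- config$mcmc
  cfg$seed <- stage_seed("mcmc")
  fit <- estimate_eap(dat, config$J, config$I, config$R, config$K,
                      mask = mask, config = cfg)

  tidyr::expand_grid(index = config$error_index, scope = config$error_scope) |>
    dplyr::mutate(error = purrr::map2_dbl(
      .data$index, .data$scope,
      function(ix, sc) compute_error(fit$estimates, emb$params, ix, sc, mask)))
}

# run a replication with one retried fresh seed, NULL (with a warning) on
# repeated failure -- failures are never silently dropped
run_replication_safely <- function(config, C_R, C_I, rep, calibration) {
  tryCatch(
    run_replication(config, C_R, C_I, rep, calibration),
    error = function(e1) {
      retry <- config
      retry$seed <- derive_seed(config$seed, C_R, C_I, rep, "retry")
      tryCatch(
        run_replication(retry, C_R, C_I, rep, calibration),
        error = function(e2) {
          warn(sprintf(
            "Replication %d of cell (C_R=%d, C_I=%d) failed twice and was excluded: %s",
            rep, C_R, C_I, conditionMessage(e2)))
          NULL
        })
    })
}

collect_errors <- function(config, C_R, C_I, calibration) {
  res <- purrr::map(seq_len(config$replications), function(rp) {
    out <- run_replication_safely(config, C_R, C_I, rp, calibration)
    if (!is.null(out)) out$rep <- rp
    out
  })
  dplyr::bind_rows(res)
}

#' Calibration threshold for a grid cell
#'
#' Reruns the replication procedure with the new test regenerated from the
#' base-test distributions — the completely linked reference condition, where
#' any residual error is pure estimation noise. The threshold is
#' `delta = mu_e + 2 * sigma_e`, the mean plus twice the sample SD (n - 1
#' denominator) of the calibration errors: a cell links accurately when its
#' mean error stays below the level that estimation noise alone reaches 95%
#' of the time. `delta` depends on the data size and on `(C_R, C_I)`, not on
#' the new test's distribution shift.
#'
#' @inheritParams run_replication
#' @return A tibble with columns `index`, `scope`, `mu`, `sigma`, `delta`,
#'   `n_reps`, plus the per-replication errors in attribute `"errors"`.
#' @export
compute_threshold <- function(config, C_R, C_I) {
  errs <- collect_errors(config, C_R, C_I, calibration = TRUE)
  out <- errs |>
    dplyr::summarise(mu = mean(.data$error), sigma = sd(.data$error),
                     n_reps = dplyr::n(), .by = c("index", "scope")) |>
    dplyr::mutate(delta = .data$mu + 2 * .data$sigma)
  attr(out, "errors") <- errs
  out
}

#' Evaluate linking accuracy over a grid of commonality counts
#'
#' For every `(C_R, C_I)` cell of the configured grid: compute the
#' calibration threshold, run the configured number of target replications,
#' and flag the cell as passing when the mean error falls below the
#' threshold. All replication seeds are pre-derived from the master seed, so
#' cells are independent and the report is reproducible regardless of
#' execution order.
#'
#' @param config An [experiment_config()].
#' @param verbose Print one progress line per cell.
#'
#' @return A `grid_report` tibble with columns `C_R`, `C_I`, `index`,
#'   `scope`, `mean_error`, `delta`, `pass`, `n_reps`; per-replication
#'   errors are kept in attribute `"errors"`. Methods: [format_grid()],
#'   `autoplot()`.
#' @export
run_grid <- function(config, verbose = FALSE) {
  cells <- tidyr::expand_grid(C_R = config$C_R, C_I = config$C_I)
  all_errs <- list()
  rows <- purrr::pmap(cells, function(C_R, C_I) {
    if (verbose) message(sprintf("cell C_R=%d C_I=%d", C_R, C_I))
    thr <- compute_threshold(config, C_R, C_I)
    errs <- collect_errors(config, C_R, C_I, calibration = FALSE)
    all_errs[[length(all_errs) + 1]] <<- dplyr::mutate(errs, C_R = C_R, C_I = C_I)
    errs |>
      dplyr::summarise(mean_error = mean(.data$error), n_reps = dplyr::n(),
                       .by = c("index", "scope")) |>
      dplyr::left_join(dplyr::select(thr, "index", "scope", "delta"),
                       by = c("index", "scope")) |>
      dplyr::mutate(C_R = C_R, C_I = C_I, pass = .data$mean_error < .data$delta)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::select("C_R", "C_I", "index", "scope", "mean_error", "delta",
                  "pass", "n_reps")
  attr(out, "errors") <- dplyr::bind_rows(all_errs)
  class(out) <- c("grid_report", class(out))
  out
}

#' Format a grid report as a text table
#'
#' One row per `C_R`, one column per `C_I`; each cell shows the mean error
#' with the threshold in parentheses, and a `*` marks cells whose mean error
#' beats the threshold (accurate linking).
#'
#' @param report A [run_grid()] result.
#' @param index,scope Which error to display (defaults: first present).
#' @return A character vector of table lines, invisibly printed.
#' @export
format_grid <- function(report, index = report$index[1], scope = report$scope[1]) {
  df <- report[report$index == index & report$scope == scope, ]
  crs <- sort(unique(df$C_R))
  cis <- sort(unique(df$C_I))
  fmt <- function(cr, ci) {
    r <- df[df$C_R == cr & df$C_I == ci, ]
    sprintf("%s%.4f(%.4f)", if (r$pass) "*" else " ", r$mean_error, r$delta)
  }
  header <- paste0(sprintf("%-6s", "C_R"),
                   paste(sprintf("%16s", paste0("C_I=", cis)), collapse = ""))
  body <- vapply(crs, function(cr) {
    paste0(sprintf("%-6d", cr),
           paste(sprintf("%16s", vapply(cis, function(ci) fmt(cr, ci),
                                        character(1))), collapse = ""))
  }, character(1))
  lines <- c(sprintf("%s over %s ('*' = accurate linking, mean < delta)",
                     index, scope), header, body)
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @describeIn run_grid Heat-map of mean error by cell; passing cells get a
#'   bold outline, labels show mean error over threshold.
#' @param object A `grid_report`.
#' @param ... Unused.
#' @export
autoplot.grid_report <- function(object, ...) {
  df <- object[object$index == object$index[1] & object$scope == object$scope[1], ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$C_I), y = factor(.data$C_R))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$mean_error), colour = "grey40") +
    ggplot2::geom_tile(data = df[df$pass, ], fill = NA, colour = "black",
                       linewidth = 1) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f\n(%.3f)", .data$mean_error, .data$delta)),
      size = 3) +
    ggplot2::scale_fill_gradient(low = "#d7ecd9", high = "#c23b22") +
    ggplot2::labs(x = "common tasks C_I", y = "common raters C_R",
                  fill = df$index[1]) +
    ggplot2::theme_minimal()
}
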