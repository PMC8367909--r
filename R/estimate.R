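#' MCMC sampler configuration
#'
#' Settings for the Metropolis-within-Gibbs sampler used for expected a
#' posteriori (EAP) estimation. The defaults (one chain, 5000 iterations,
#' 2000 burn-in, thinning 2) suit the small/mid-sized posteriors that arise
#' here (at most a few hundred parameters, unimodal in practice); everything
#' is overridable. Proposal SDs are starting values only — they are adapted
#' toward a 20-50% acceptance rate during burn-in and then frozen.
#'
#' @param iterations Total sweeps.
#' @param burn_in Sweeps discarded before retention; must be < `iterations`.
#' @param thinning Keep every `thinning`-th post-burn-in sweep.
#' @param chains Number of independent chains (draws are pooled).
#' @param proposal_sd Named numeric vector of initial random-walk SDs for
#'   classes `theta`, `beta`, `gamma`, `d`.
#' @param seed Optional integer seed; if `NULL` the current R stream is used.
#'
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(iterations = 5000, burn_in = 2000, thinning = 2,
                        chains = 1,
                        proposal_sd = c(theta = 0.35, beta = 0.12,
                                        gamma = 0.12, d = 0.08),
                        seed = NULL) {
  if (burn_in >= iterations) {
    abort("burn_in must be smaller than iterations.", class = "facetlink_config_error")
  }
  if (chains < 1) abort("chains must be >= 1.", class = "facetlink_config_error")
  if (any(proposal_sd <= 0)) {
    abort("proposal SDs must be positive.", class = "facetlink_config_error")
  }
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 chains = as.integer(chains),
                 proposal_sd = proposal_sd, seed = seed),
            class = "mcmc_config")
}

#' Fixed-anchor mask for linked estimation
#'
#' Records which rater (gamma) and task (beta) parameters are held fixed —
#' and at which values — while the new test is estimated. Usually built from
#' the [embed_common()] layout, whose anchor values come from the base test.
#'
#' @param layout A `linking_layout`, or `NULL` to specify indices directly.
#' @param gamma_idx,gamma_val,beta_idx,beta_val Explicit fixed indices (into
#'   the new test's vectors) and values, used when `layout` is `NULL`.
#'
#' @return A `fixed_mask` list with elements `gamma_idx`, `gamma_val`,
#'   `beta_idx`, `beta_val`.
#' @export
fixed_mask <- function(layout = NULL, gamma_idx = integer(0),
                       gamma_val = numeric(0), beta_idx = integer(0),
                       beta_val = numeric(0)) {
  if (!is.null(layout)) {
    gamma_idx <- layout$common_raters$new
    gamma_val <- layout$common_raters$value
    beta_idx <- layout$common_tasks$new
    beta_val <- layout$common_tasks$value
  }
  if (length(gamma_idx) != length(gamma_val) ||
      length(beta_idx) != length(beta_val)) {
    abort("Fixed indices and values must have equal lengths.",
          class = "facetlink_invalid_layout")
  }
  if (!all(is.finite(gamma_val)) || !all(is.finite(beta_val))) {
    abort("Fixed anchor values must be finite.", class = "facetlink_invalid_layout")
  }
  structure(list(gamma_idx = as.integer(gamma_idx), gamma_val = gamma_val,
                 beta_idx = as.integer(beta_idx), beta_val = beta_val),
            class = "fixed_mask")
}

mask_is_empty <- function(mask) {
  is.null(mask) || (length(mask$gamma_idx) == 0L && length(mask$beta_idx) == 0L)
}

#' Log-posterior of an MFRM parameter set
#'
#' Log-likelihood of the rating data plus independent standard-normal
#' log-prior terms over the free parameters: all theta, the non-anchored
#' beta and gamma, and the K - 2 free category components `d[2..K-1]`
#' (`d[1]` is structural and `d[K]` is determined by the sum-to-zero
#' constraint). Anchored entries contribute likelihood but no prior.
#'
#' @param data Long-format rating tibble (see [mfrm_loglik()]).
#' @param params An [mfrm_params()] object; anchored entries must equal
#'   their fixed values exactly.
#' @param mask A [fixed_mask()] or `NULL`.
#'
#' @return Scalar log-posterior (unnormalized).
#' @export
log_posterior <- function(data, params, mask = NULL) {
  if (!mask_is_empty(mask)) {
    if (any(params$gamma[mask$gamma_idx] != mask$gamma_val) ||
        any(params$beta[mask$beta_idx] != mask$beta_val)) {
      abort("Masked parameters deviate from their fixed anchor values.",
            class = "facetlink_contract_violation")
    }
  }
  free_beta <- setdiff(seq_len(params$I), if (is.null(mask)) integer(0) else mask$beta_idx)
  free_gamma <- setdiff(seq_len(params$R), if (is.null(mask)) integer(0) else mask$gamma_idx)
  free_d <- if (params$K > 2) params$d[2:(params$K - 1)] else numeric(0)
  mfrm_loglik(data, params) +
    sum(dnorm(params$theta, log = TRUE)) +
    sum(dnorm(params$beta[free_beta], log = TRUE)) +
    sum(dnorm(params$gamma[free_gamma], log = TRUE)) +
    sum(dnorm(free_d, log = TRUE))
}

#' EAP estimation of MFRM parameters by MCMC
#'
#' Estimates all free parameters of an MFRM from long-format rating data by
#' the posterior mean (EAP) of Metropolis-within-Gibbs draws, under standard
#' normal priors. Two identification regimes:
#' * anchored fit (`mask` non-empty): the anchored gamma/beta are held at
#'   their fixed values, which resolves the location indeterminacy, and the
#'   usual `gamma[1] = 0` constraint is *not* imposed — this is the fixed
#'   common-parameter linking method;
#' * stand-alone fit (`mask` empty): `gamma[1]` is pinned to 0 for
#'   identification.
#'
#' Every retained draw satisfies `d[1] = 0` and `sum(d[2..K]) = 0` exactly
#' (the sampler walks on the K - 2 free components and derives `d[K]`).
#'
#' @param data Rating tibble with columns `examinee`, `task`, `rater`,
#'   `score`.
#' @param J,I,R,K Model dimensions.
#' @param mask A [fixed_mask()] of anchors, or `NULL`.
#' @param config An [mcmc_config()].
#'
#' @return An `mfrm_fit` object: list with `estimates` ([mfrm_params()]),
#'   `draws` (pooled matrices per class), `diagnostics` (acceptance rates,
#'   adapted proposal SDs, split-half convergence statistic per class) and
#'   the call's `config`/`mask`. Methods: [tidy.mfrm_fit()],
#'   [glance.mfrm_fit()], `autoplot()`.
#' @examples
#' set.seed(2)
#' p <- generate_parameters(J = 10, I = 3, R = 3, K = 3)
#' dat <- sample_dataset(p)
#' fit <- estimate_eap(dat, J = 10, I = 3, R = 3, K = 3,
#'                     config = mcmc_config(iterations = 600, burn_in = 200))
#' glance(fit)
#' @export
estimate_eap <- function(data, J, I, R, K, mask = NULL, config = mcmc_config()) {
  template <- mfrm_params(rep(0, J), rep(0, I), rep(0, R),
                          d = rep(0, K))
  check_rating_data(data, template)
  if (any(duplicated(data[c("examinee", "task", "rater")]))) {
    abort("At most one record per (examinee, task, rater) triple.",
          class = "facetlink_data_error")
  }

  beta_fixed <- rep(FALSE, I)
  gamma_fixed <- rep(FALSE, R)
  beta0 <- rep(0, I)
  gamma0 <- rep(0, R)
  if (!mask_is_empty(mask)) {
    beta_fixed[mask$beta_idx] <- TRUE
    beta0[mask$beta_idx] <- mask$beta_val
    gamma_fixed[mask$gamma_idx] <- TRUE
    gamma0[mask$gamma_idx] <- mask$gamma_val
  } else {
    gamma_fixed[1] <- TRUE # gamma[1] = 0 identification pin
  }

  # connectivity diagnostics: parameters with no observations lean on priors
  n_by_rater <- tabulate(data$rater, R)
  n_by_task <- tabulate(data$task, I)
  if (any(n_by_rater[!gamma_fixed] == 0L) || any(n_by_task[!beta_fixed] == 0L)) {
    warn("Some free parameters have no observations; their estimates are prior-dominated.")
  }

  if (!is.null(config$seed)) set.seed(config$seed)
  runs <- purrr::map(seq_len(config$chains), function(ch) {
    mfrm_mwg(as.integer(data$examinee) - 1L, as.integer(data$task) - 1L,
             as.integer(data$rater) - 1L, as.integer(data$score),
             J, I, R, K, rep(0, J), beta0, gamma0, rep(0, K),
             beta_fixed, gamma_fixed,
             config$iterations, config$burn_in, config$thinning,
             as.numeric(config$proposal_sd[c("theta", "beta", "gamma", "d")]))
  })

  draws <- purrr::map(setNames(c("theta", "beta", "gamma", "d"),
                               c("theta", "beta", "gamma", "d")),
                      function(cl) do.call(rbind, purrr::map(runs, cl)))
  est_d <- colMeans(draws$d)
  if (K > 2) est_d[K] <- -sum(est_d[2:(K - 1)]) else est_d[K] <- 0
  est_d[1] <- 0
  estimates <- mfrm_params(colMeans(draws$theta), colMeans(draws$beta),
                           colMeans(draws$gamma), est_d)
  # anchored entries reported exactly at their fixed values
  estimates$beta[beta_fixed] <- beta0[beta_fixed]
  estimates$gamma[gamma_fixed] <- gamma0[gamma_fixed]

  acceptance <- colMeans(do.call(rbind, purrr::map(runs, "acceptance")))
  diagnostics <- list(
    acceptance = acceptance,
    prop_sd = runs[[length(runs)]]$prop_sd,
    split_rhat = purrr::map_dbl(draws, split_rhat_max),
    n_draws = nrow(draws$theta)
  )
  structure(list(estimates = estimates, draws = draws,
                 diagnostics = diagnostics, config = config, mask = mask,
                 beta_fixed = beta_fixed, gamma_fixed = gamma_fixed,
                 n_records = nrow(data)),
            class = "mfrm_fit")
}

# max split-half potential-scale-reduction over the columns of a draw matrix
split_rhat_max <- function(m) {
  n <- nrow(m)
  if (n < 4) return(NA_real_)
  h <- n %/% 2
  a <- m[seq_len(h), , drop = FALSE]
  b <- m[(n - h + 1):n, , drop = FALSE]
  w <- (apply(a, 2, var) + apply(b, 2, var)) / 2
  bb <- h * (colMeans(a) - colMeans(b))^2 / 2
  ok <- w > 1e-12
  if (!any(ok)) return(1)
  max(sqrt(((h - 1) / h * w[ok] + bb[ok] / h) / w[ok]))
}

# Monte-Carlo standard error by batch means, per column
mcse_batch <- function(m, n_batch = 25) {
  n <- nrow(m)
  n_batch <- min(n_batch, max(2, n %/% 4))
  size <- n %/% n_batch
  idx <- rep(seq_len(n_batch), each = size)
  means <- apply(m[seq_along(idx), , drop = FALSE], 2,
                 function(col) tapply(col, idx, mean))
  apply(means, 2, sd) / sqrt(n_batch)
}

#' @describeIn estimate_eap Tidy the fit: one row per parameter with columns
#'   `class`, `index`, `estimate`, `post_sd` (posterior SD), `mcse`
#'   (batch-means Monte-Carlo standard error of the EAP) and `fixed`.
#' @param x An `mfrm_fit`.
#' @param ... Unused.
#' @export
tidy.mfrm_fit <- function(x, ...) {
  est <- dplyr::rename(tidy(x$estimates), estimate = "value")
  est$post_sd <- c(apply(x$draws$theta, 2, sd), apply(x$draws$beta, 2, sd),
                   apply(x$draws$gamma, 2, sd), apply(x$draws$d, 2, sd))
  est$mcse <- c(mcse_batch(x$draws$theta), mcse_batch(x$draws$beta),
                mcse_batch(x$draws$gamma), mcse_batch(x$draws$d))
  p <- x$estimates
  est$fixed <- c(rep(FALSE, p$J), x$beta_fixed, x$gamma_fixed,
                 c(TRUE, rep(FALSE, p$K - 2), TRUE)[seq_len(p$K)])
  est
}

#' @describeIn estimate_eap One-row summary: record count, sampler settings,
#'   pooled draw count, per-class acceptance rates and the largest
#'   split-half convergence statistic.
#' @export
glance.mfrm_fit <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records,
    iterations = x$config$iterations, burn_in = x$config$burn_in,
    thinning = x$config$thinning, chains = x$config$chains,
    n_draws = x$diagnostics$n_draws,
    accept_theta = unname(x$diagnostics$acceptance["theta"]),
    accept_beta = unname(x$diagnostics$acceptance["beta"]),
    accept_gamma = unname(x$diagnostics$acceptance["gamma"]),
    accept_d = unname(x$diagnostics$acceptance["d"]),
    max_split_rhat = max(x$diagnostics$split_rhat, na.rm = TRUE)
  )
}

#' @export
print.mfrm_fit <- function(x, ...) {
  p <- x$estimates
  cat(sprintf("<mfrm_fit> EAP estimates from %d records (J=%d, I=%d, R=%d, K=%d)\n",
              x$n_records, p$J, p$I, p$R, p$K))
  cat(sprintf("  %d pooled draws; acceptance: %s; max split-Rhat %.3f\n",
              x$diagnostics$n_draws,
              paste(sprintf("%s %.2f", names(x$diagnostics$acceptance),
                            x$diagnostics$acceptance), collapse = ", "),
              max(x$diagnostics$split_rhat, na.rm = TRUE)))
  invisible(x)
}

#' @describeIn estimate_eap Caterpillar plot of EAP estimates with
#'   approximate 95% posterior intervals, faceted by parameter class.
#' @param object An `mfrm_fit`.
#' @export
autoplot.mfrm_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$index, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 1.96 * .data$post_sd,
      ymax = .data$estimate + 1.96 * .data$post_sd,
      colour = .data$fixed), linewidth = 0.3, size = 0.2) +
    ggplot2::facet_wrap(~class, scales = "free_x") +
    ggplot2::labs(x = "parameter index", y = "EAP estimate (logits)",
                  colour = "anchored") +
    ggplot2::theme_minimal()
}
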