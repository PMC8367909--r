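#' Specify generating distributions for the four MFRM parameter classes
#'
#' Each class (theta, beta, gamma, d) is drawn from its own normal
#' distribution. The default — every class standard normal — is the reference
#' (base-test) condition; shifted new-test conditions move one or more class
#' means.
#'
#' @param theta_mean,theta_sd,beta_mean,beta_sd,gamma_mean,gamma_sd,d_mean,d_sd
#'   Means and standard deviations (logits); all SDs must be positive.
#'
#' @return A `distribution_spec` tibble with columns `class`, `mean`, `sd`.
#' @examples
#' distribution_spec(theta_mean = -0.5)
#' @export
distribution_spec <- function(theta_mean = 0, theta_sd = 1,
                              beta_mean = 0, beta_sd = 1,
                              gamma_mean = 0, gamma_sd = 1,
                              d_mean = 0, d_sd = 1) {
  out <- tibble::tibble(
    class = c("theta", "beta", "gamma", "d"),
    mean = c(theta_mean, beta_mean, gamma_mean, d_mean),
    sd = c(theta_sd, beta_sd, gamma_sd, d_sd)
  )
  if (any(!is.finite(out$mean)) || any(!is.finite(out$sd)) || any(out$sd <= 0)) {
    abort("Distribution means must be finite and SDs positive.",
          class = "facetlink_config_error")
  }
  class(out) <- c("distribution_spec", class(out))
  out
}

#' Canonical new-test distribution-shift scenarios
#'
#' The four shift conditions studied for the new test, numbered 1-4:
#' 1. ability shift, theta ~ N(-0.5, 1), other classes standard normal;
#' 2. smaller ability shift, theta ~ N(-0.2, 1);
#' 3. ability shift plus task shift, beta ~ N(0.5, 1);
#' 4. ability shift plus rater shift, gamma ~ N(0.5, 1).
#'
#' @param scenario Integer 1-4.
#' @return A [distribution_spec()].
#' @export
scenario_spec <- function(scenario) {
  if (!scenario %in% 1:4) {
    abort("scenario must be 1, 2, 3 or 4.", class = "facetlink_config_error")
  }
  switch(scenario,
    distribution_spec(theta_mean = -0.5),
    distribution_spec(theta_mean = -0.2),
    distribution_spec(theta_mean = -0.5, beta_mean = 0.5),
    distribution_spec(theta_mean = -0.5, gamma_mean = 0.5)
  )
}

spec_row <- function(spec, cls) {
  r <- spec[spec$class == cls, ]
  list(mean = r$mean, sd = r$sd)
}

#' Generate true MFRM parameters for one test
#'
#' Draws theta, beta and gamma i.i.d. from their class distributions. For the
#' category parameters, K - 1 values are drawn from the d distribution,
#' sorted ascending (thresholds are expected to be ordered in practice), and
#' mean-centered so they total zero; they become `d[2..K]` with `d[1] = 0`.
#' Uses the current R random stream; call `set.seed()` first for
#' reproducibility.
#'
#' @param J,I,R Numbers of examinees, tasks, raters.
#' @param K Number of rating categories (default 5).
#' @param spec A [distribution_spec()].
#'
#' @return An [mfrm_params()] object.
#' @examples
#' set.seed(1)
#' generate_parameters(J = 20, I = 4, R = 3)
#' @export
generate_parameters <- function(J, I, R, K = 5, spec = distribution_spec()) {
  if (K < 2) abort("K must be at least 2.", class = "facetlink_config_error")
  th <- spec_row(spec, "theta"); be <- spec_row(spec, "beta")
  ga <- spec_row(spec, "gamma"); dd <- spec_row(spec, "d")
  theta <- rnorm(J, th$mean, th$sd)
  beta <- rnorm(I, be$mean, be$sd)
  gamma <- rnorm(R, ga$mean, ga$sd)
  draws <- sort(rnorm(K - 1, dd$mean, dd$sd))
  d_tail <- draws - mean(draws)
  # exact zero total despite float centering
  d_tail[K - 1] <- -sum(d_tail[-(K - 1)])
  mfrm_params(theta, beta, gamma, d = c(0, d_tail))
}

#' Embed common raters and tasks from a base test into a new test
#'
#' Selects `C_R` raters and `C_I` tasks uniformly at random (without
#' replacement) from the base test, an equal number of slots uniformly at
#' random from the new test, and overwrites the new test's gamma/beta values
#' at those slots with the base values. The returned layout records the
#' base-to-new index mapping and the anchor values that will be held fixed
#' when the new test is estimated.
#'
#' @param base,new [mfrm_params()] objects for the two tests.
#' @param C_R,C_I Numbers of common raters and tasks;
#'   `0 <= C_R <= min(R)`, `0 <= C_I <= min(I)`.
#'
#' @return A list with elements `params` (the new test with commons embedded)
#'   and `layout`, a `linking_layout`: list with tibbles `common_raters` and
#'   `common_tasks` (columns `base`, `new`, `value`) and counts `C_R`, `C_I`.
#' @export
embed_common <- function(base, new, C_R, C_I) {
  if (C_R < 0 || C_R > min(base$R, new$R) || C_I < 0 || C_I > min(base$I, new$I)) {
    abort("C_R and C_I must lie within both tests' rater/task counts.",
          class = "facetlink_invalid_layout")
  }
  base_r <- if (C_R > 0) sample(base$R, C_R) else integer(0)
  base_i <- if (C_I > 0) sample(base$I, C_I) else integer(0)
  new_r <- if (C_R > 0) sample(new$R, C_R) else integer(0)
  new_i <- if (C_I > 0) sample(new$I, C_I) else integer(0)
  params <- new
  params$gamma[new_r] <- base$gamma[base_r]
  params$beta[new_i] <- base$beta[base_i]
  anchor_g <- base$gamma[base_r]
  anchor_b <- base$beta[base_i]
  layout <- structure(
    list(
      C_R = C_R, C_I = C_I,
      common_raters = tibble::tibble(base = base_r, new = new_r,
                                     value = anchor_g),
      common_tasks = tibble::tibble(base = base_i, new = new_i,
                                    value = anchor_b)
    ),
    class = "linking_layout"
  )
  list(params = params, layout = layout)
}

#' @export
print.linking_layout <- function(x, ...) {
  cat(sprintf("<linking_layout> C_R = %d common raters, C_I = %d common tasks\n",
              x$C_R, x$C_I))
  invisible(x)
}

#' Inject drift into common rater/task parameters (sampling-only copy)
#'
#' Simulates rater drift and task (item) drift between test administrations:
#' about half of the common entities receive a small additive zero-mean
#' normal fluctuation before the new test's data are sampled. The number of
#' drifted tasks is `floor(C_I / 2) + C_I %% 2` and of drifted raters
#' `floor((C_R - 1) / 2) + (C_R - 1) %% 2`; drifted entities are chosen
#' uniformly among the commons. The returned copy is meant only for sampling
#' rating data — estimation keeps the undrifted anchor values recorded in the
#' layout, which is precisely what makes drift degrade linking.
#'
#' @param new An [mfrm_params()] object with commons embedded.
#' @param layout The `linking_layout` from [embed_common()].
#' @param sd_task,sd_rater Fluctuation SDs (logits); defaults 0.05 and 0.10,
#'   in line with reported magnitudes of item and rater drift.
#'
#' @return An `mfrm_params` copy with drifted beta/gamma at some common
#'   slots; all other entries (and d) are bit-identical to `new`.
#' @export
inject_drift <- function(new, layout, sd_task = 0.05, sd_rater = 0.10) {
  n_task <- (layout$C_I %/% 2) + (layout$C_I %% 2)
  n_rater <- ((layout$C_R - 1) %/% 2) + ((layout$C_R - 1) %% 2)
  out <- new
  if (n_task > 0) {
    slots <- layout$common_tasks$new[sample.int(layout$C_I, n_task)]
    out$beta[slots] <- out$beta[slots] + rnorm(n_task, 0, sd_task)
  }
  if (n_rater > 0) {
    slots <- layout$common_raters$new[sample.int(layout$C_R, n_rater)]
    out$gamma[slots] <- out$gamma[slots] + rnorm(n_rater, 0, sd_rater)
  }
  out
}

#' Sample a rating dataset from an MFRM parameter set
#'
#' Draws one score per assigned examinee-task-rater triple. With
#' `design = NULL` the design is complete: every rater rates every examinee
#' on every task (`J * I * R` records, in examinee, task, rater order).
#' Otherwise records follow the rows of the [build_design()] table, and
#' unassigned triples are simply absent (missing by design).
#'
#' @param params An [mfrm_params()] object.
#' @param design A `rater_design`, or `NULL` for complete data.
#'
#' @return A tibble with columns `examinee`, `task`, `rater`, `score`.
#' @examples
#' set.seed(7)
#' p <- generate_parameters(J = 5, I = 2, R = 3)
#' sample_dataset(p)
#' @export
sample_dataset <- function(params, design = NULL) {
  if (is.null(design)) {
    triples <- tidyr::expand_grid(examinee = seq_len(params$J),
                                  task = seq_len(params$I),
                                  rater = seq_len(params$R))
  } else {
    if (attr(design, "J") != params$J || attr(design, "I") != params$I ||
        attr(design, "R") != params$R) {
      abort("Design dimensions do not match the parameter set.",
            class = "facetlink_data_error")
    }
    triples <- tibble::tibble(examinee = design$examinee, task = design$task,
                              rater = design$rater)
  }
  eta <- params$theta[triples$examinee] - params$beta[triples$task] -
    params$gamma[triples$rater]
  triples$score <- sample_response(eta, params$d, params$K)
  triples
}
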