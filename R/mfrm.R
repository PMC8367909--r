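#' Construct a set of many-facet Rasch model parameters
#'
#' Bundles the four parameter classes of the MFRM: examinee abilities
#' \eqn{\theta_j}, task difficulties \eqn{\beta_i}, rater severities
#' \eqn{\gamma_r}, and category-transition parameters \eqn{d_k}, all on the
#' logit scale. The category parameters carry two structural constraints:
#' \eqn{d_1 = 0} and \eqn{\sum_{k \ge 2} d_k = 0}.
#'
#' @param theta Numeric vector of J examinee abilities (logits).
#' @param beta Numeric vector of I task difficulties (logits).
#' @param gamma Numeric vector of R rater severities (logits).
#' @param d Numeric vector of K category parameters; `d[1]` must be exactly 0
#'   and `d[2..K]` must sum to 0 (tolerance `1e-12`).
#'
#' @return An object of class `mfrm_params`: a list with elements `theta`,
#'   `beta`, `gamma`, `d` and the dimensions `J`, `I`, `R`, `K`.
#' @examples
#' p <- mfrm_params(theta = c(0, 1), beta = 0.2, gamma = c(-0.1, 0.1),
#'                  d = c(0, -0.5, 0.5))
#' tidy(p)
#' @export
mfrm_params <- function(theta, beta, gamma, d) {
  theta <- as.numeric(theta)
  beta <- as.numeric(beta)
  gamma <- as.numeric(gamma)
  d <- as.numeric(d)
  out <- structure(
    list(theta = theta, beta = beta, gamma = gamma, d = d,
         J = length(theta), I = length(beta), R = length(gamma),
         K = length(d)),
    class = "mfrm_params"
  )
  validate_mfrm_params(out)
  out
}

validate_mfrm_params <- function(p) {
  if (!all(vapply(p[c("theta", "beta", "gamma", "d")],
                  function(v) all(is.finite(v)), logical(1)))) {
    abort("All MFRM parameter values must be finite.", class = "facetlink_invalid_input")
  }
  if (p$K < 2) {
    abort("At least K = 2 rating categories are required.", class = "facetlink_invalid_input")
  }
  if (p$d[1] != 0) {
    abort("Category parameter d[1] must be exactly 0.", class = "facetlink_invalid_input")
  }
  if (abs(sum(p$d[-1])) > 1e-12) {
    abort("Category parameters d[2..K] must sum to 0 (tolerance 1e-12).",
          class = "facetlink_invalid_input")
  }
  invisible(p)
}

#' @export
print.mfrm_params <- function(x, ...) {
  cat(sprintf("<mfrm_params> J = %d examinees, I = %d tasks, R = %d raters, K = %d categories\n",
              x$J, x$I, x$R, x$K))
  cat(sprintf("  theta: mean %+.3f sd %.3f | beta: mean %+.3f | gamma: mean %+.3f\n",
              mean(x$theta), stats::sd(x$theta), mean(x$beta), mean(x$gamma)))
  cat("  d: ", paste(sprintf("%+.3f", x$d), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn mfrm_params Tidy a parameter set into a long tibble with
#'   columns `class` (`"theta"`, `"beta"`, `"gamma"`, `"d"`), `index`
#'   (1-based) and `value`.
#' @param x An `mfrm_params` object.
#' @param ... Unused.
#' @export
tidy.mfrm_params <- function(x, ...) {
  tibble::tibble(
    class = rep(c("theta", "beta", "gamma", "d"), c(x$J, x$I, x$R, x$K)),
    index = c(seq_len(x$J), seq_len(x$I), seq_len(x$R), seq_len(x$K)),
    value = c(x$theta, x$beta, x$gamma, x$d)
  )
}

#' MFRM rating-category probabilities
#'
#' Probability of each rating category `1..K` under the adjacent-categories
#' many-facet Rasch model, for a given combined logit
#' `eta = theta_j - beta_i - gamma_r`. Category `k` has unnormalized log-mass
#' \eqn{\sum_{m \le k} (\eta - d_m) = k\,\eta - D_k} with
#' \eqn{D_k = \sum_{m \le k} d_m}; probabilities are normalized over the K
#' categories. The computation subtracts the maximum cumulative sum before
#' exponentiation, so it is stable for `|eta|` up to the drifted-parameter
#' range (roughly 8 logits) and beyond.
#'
#' @param eta Numeric vector of combined logits.
#' @param d Category parameter vector (see [mfrm_params()]).
#' @param K Number of categories; defaults to `length(d)` and must match it.
#'
#' @return If `eta` is scalar, a probability vector of length K summing to 1;
#'   otherwise a `length(eta) x K` matrix with one row per logit.
#' @examples
#' category_probabilities(0, d = c(0, -0.5, 0.5))
#' @export
category_probabilities <- function(eta, d, K = length(d)) {
  if (!all(is.finite(eta)) || !all(is.finite(d))) {
    abort("eta and d must be finite.", class = "facetlink_invalid_input")
  }
  if (K != length(d)) {
    abort(sprintf("K = %d does not match length(d) = %d.", K, length(d)),
          class = "facetlink_dimension_error")
  }
  Dc <- cumsum(d)
  # s[n, k] = k * eta_n - D_k, stabilized per row
  s <- outer(eta, seq_len(K)) - matrix(Dc, length(eta), K, byrow = TRUE)
  s <- s - apply(s, 1, max)
  e <- exp(s)
  p <- e / rowSums(e)
  if (length(eta) == 1L) drop(p) else p
}

#' Expected score under the MFRM
#'
#' @param eta Numeric vector of combined logits.
#' @inheritParams category_probabilities
#' @return Numeric vector of expected rating scores, in `[1, K]`.
#' @export
expected_score <- function(eta, d, K = length(d)) {
  p <- category_probabilities(eta, d, K)
  if (is.null(dim(p))) sum(seq_len(K) * p) else drop(p %*% seq_len(K))
}

#' Log-likelihood of a rating table under an MFRM parameter set
#'
#' Sums the log category probability over the observed records of a
#' long-format rating table. Missing (unassigned) examinee-task-rater triples
#' are simply absent from the table and contribute nothing.
#'
#' @param data A data frame with integer columns `examinee`, `task`, `rater`,
#'   `score` (1-based ids, scores in `1..K`).
#' @param params An [mfrm_params()] object whose dimensions cover the ids in
#'   `data`.
#'
#' @return A single numeric log-likelihood value (0 for an empty table).
#' @export
mfrm_loglik <- function(data, params) {
  check_rating_data(data, params)
  if (nrow(data) == 0L) return(0)
  eta <- params$theta[data$examinee] - params$beta[data$task] -
    params$gamma[data$rater]
  Dc <- cumsum(params$d)
  K <- params$K
  s <- outer(eta, seq_len(K)) - matrix(Dc, length(eta), K, byrow = TRUE)
  m <- apply(s, 1, max)
  lse <- m + log(rowSums(exp(s - m)))
  sum(s[cbind(seq_along(eta), data$score)] - lse)
}

check_rating_data <- function(data, params) {
  req <- c("examinee", "task", "rater", "score")
  if (!all(req %in% names(data))) {
    abort("Rating data needs columns examinee, task, rater, score.",
          class = "facetlink_data_error")
  }
  if (nrow(data) == 0L) return(invisible(data))
  if (any(data$score < 1L | data$score > params$K)) {
    abort(sprintf("Scores must lie in 1..%d.", params$K),
          class = "facetlink_data_error")
  }
  if (any(data$examinee < 1L | data$examinee > params$J) ||
      any(data$task < 1L | data$task > params$I) ||
      any(data$rater < 1L | data$rater > params$R)) {
    abort("Rating ids exceed the declared parameter dimensions.",
          class = "facetlink_data_error")
  }
  invisible(data)
}

#' Sample rating scores from the MFRM
#'
#' Draws one categorical score per supplied logit, using the current R random
#' number stream (so `set.seed()` gives exact reproducibility). Sampling is by
#' inversion of the cumulative category probabilities: one uniform draw per
#' response, taken in the order of `eta`. Because of this single-uniform
#' scheme, two parameter sets sampled under the same seed share common random
#' numbers, which pairs simulated datasets tightly (used for paired drift
#' comparisons).
#'
#' @inheritParams category_probabilities
#' @return Integer vector of scores in `1..K`, one per element of `eta`.
#' @export
sample_response <- function(eta, d, K = length(d)) {
  p <- category_probabilities(eta, d, K)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  cp <- t(apply(p, 1, cumsum))
  u <- runif(nrow(p))
  as.integer(1L + rowSums(u > cp[, -K, drop = FALSE]))
}
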