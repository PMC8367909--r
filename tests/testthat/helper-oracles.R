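# Independent brute-force oracles: direct evaluation of the adjacent-categories
# model, one record and one category at a time, with no shared code path with
# the package internals (no stabilization, explicit loops).

naive_category_probs <- function(eta, d) {
  K <- length(d)
  num <- numeric(K)
  for (k in seq_len(K)) {
    num[k] <- exp(sum(eta - d[seq_len(k)]))
  }
  num / sum(num)
}

naive_loglik <- function(data, params) {
  tot <- 0
  for (m in seq_len(nrow(data))) {
    eta <- params$theta[data$examinee[m]] - params$beta[data$task[m]] -
      params$gamma[data$rater[m]]
    p <- naive_category_probs(eta, params$d)
    tot <- tot + log(p[data$score[m]])
  }
  tot
}

naive_log_posterior <- function(data, params, mask = NULL) {
  fixed_b <- if (is.null(mask)) integer(0) else mask$beta_idx
  fixed_g <- if (is.null(mask)) integer(0) else mask$gamma_idx
  lp <- naive_loglik(data, params)
  for (v in params$theta) lp <- lp + dnorm(v, log = TRUE)
  for (i in seq_len(params$I)) {
    if (!(i %in% fixed_b)) lp <- lp + dnorm(params$beta[i], log = TRUE)
  }
  for (r in seq_len(params$R)) {
    if (!(r %in% fixed_g)) lp <- lp + dnorm(params$gamma[r], log = TRUE)
  }
  if (params$K > 2) {
    for (k in 2:(params$K - 1)) lp <- lp + dnorm(params$d[k], log = TRUE)
  }
  lp
}

# random valid category-parameter vector: d[1] = 0, tail sums to zero exactly
random_valid_d <- function(K) {
  tail <- rnorm(K - 1)
  tail <- tail - mean(tail)
  tail[K - 1] <- -sum(tail[-(K - 1)])
  c(0, tail)
}

# small random parameter set + fully crossed data for toy comparisons
toy_instance <- function(J = 4, I = 2, R = 3, K = 4, seed = 99) {
  set.seed(seed)
  p <- generate_parameters(J, I, R, K)
  list(params = p, data = sample_dataset(p))
}

# short sampler settings for structural (non-accuracy) tests
quick_mcmc <- function(seed = NULL) {
  mcmc_config(iterations = 1200, burn_in = 400, thinning = 2, seed = seed)
}
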