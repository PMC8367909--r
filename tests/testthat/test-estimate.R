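test_that("log-posterior matches closed form and the naive oracle", {
  J <- 3; I <- 2; R <- 2; K <- 4
  zero <- mfrm_params(rep(0, J), rep(0, I), rep(0, R), rep(0, K))
  empty <- tibble::tibble(examinee = integer(0), task = integer(0),
                          rater = integer(0), score = integer(0))
  n_free <- J + I + R + (K - 2)
  expect_equal(log_posterior(empty, zero), n_free * dnorm(0, log = TRUE))
  inst <- toy_instance(J = 3, I = 2, R = 2, K = 4, seed = 71)
  dat <- head(inst$data, 10)
  expect_equal(log_posterior(dat, inst$params),
               naive_log_posterior(dat, inst$params), tolerance = 1e-10)
  # with anchors: fixed entries lose their prior term
  mask <- fixed_mask(gamma_idx = 1L, gamma_val = inst$params$gamma[1],
                     beta_idx = 2L, beta_val = inst$params$beta[2])
  expect_equal(log_posterior(dat, inst$params, mask),
               naive_log_posterior(dat, inst$params, mask), tolerance = 1e-10)
  # additivity: one more record changes the value by its log-probability
  dat11 <- head(inst$data, 11)
  rec <- dat11[11, ]
  eta <- inst$params$theta[rec$examinee] - inst$params$beta[rec$task] -
    inst$params$gamma[rec$rater]
  expect_equal(log_posterior(dat11, inst$params) - log_posterior(dat, inst$params),
               log(category_probabilities(eta, inst$params$d)[rec$score]),
               tolerance = 1e-10)
  # contract: masked entries must sit at their fixed values
  bad_mask <- fixed_mask(gamma_idx = 1L, gamma_val = inst$params$gamma[1] + 1)
  expect_error(log_posterior(dat, inst$params, bad_mask),
               class = "facetlink_contract_violation")
})

test_that("with no data the EAP reproduces the prior mean", {
  empty <- tibble::tibble(examinee = integer(0), task = integer(0),
                          rater = integer(0), score = integer(0))
  expect_warning(
    fit <- estimate_eap(empty, J = 3, I = 2, R = 2, K = 3,
                        config = mcmc_config(iterations = 6000, burn_in = 1000,
                                             seed = 72)),
    "prior-dominated")
  td <- tidy(fit)
  free <- td[!td$fixed, ]
  expect_true(all(abs(free$estimate) <= 3 * free$mcse))
  # prior spread recovered too (weak check)
  expect_true(all(abs(free$post_sd - 1) < 0.2))
})

test_that("every retained draw satisfies the category constraints", {
  inst <- toy_instance(J = 8, I = 3, R = 3, K = 5, seed = 73)
  fit <- estimate_eap(inst$data, 8, 3, 3, 5, config = quick_mcmc(seed = 73))
  expect_true(all(fit$draws$d[, 1] == 0))
  expect_lt(max(abs(rowSums(fit$draws$d[, -1]))), 1e-12)
  expect_identical(fit$estimates$d[1], 0)
  expect_lt(abs(sum(fit$estimates$d[-1])), 1e-12)
})

test_that("single-parameter EAP agrees with numerical quadrature", {
  # one examinee, one task, one rater, K = 2; beta and gamma anchored at 0,
  # so the posterior over theta is 1-D: phi(theta) * P(x | theta)
  dat <- tibble::tibble(examinee = 1L, task = 1L, rater = 1L, score = 2L)
  mask <- fixed_mask(gamma_idx = 1L, gamma_val = 0, beta_idx = 1L, beta_val = 0)
  fit <- estimate_eap(dat, J = 1, I = 1, R = 1, K = 2, mask = mask,
                      config = mcmc_config(iterations = 20000, burn_in = 2000,
                                           seed = 74))
  lik <- function(th) vapply(th, function(t) {
    category_probabilities(t, c(0, 0))[2]
  }, numeric(1))
  num <- stats::integrate(function(t) t * dnorm(t) * lik(t), -8, 8)$value
  den <- stats::integrate(function(t) dnorm(t) * lik(t), -8, 8)$value
  expect_lt(abs(fit$estimates$theta - num / den), 0.05)
})

test_that("a stand-alone fit recovers truth better than the prior mean", {
  set.seed(75)
  truth <- generate_parameters(J = 30, I = 5, R = 5, K = 5)
  # impose the stand-alone identification on the truth: gamma[1] = 0
  shift <- truth$gamma[1]
  truth$gamma <- truth$gamma - shift
  truth$theta <- truth$theta - shift
  dat <- sample_dataset(truth)
  fit <- estimate_eap(dat, 30, 5, 5, 5,
                      config = mcmc_config(iterations = 3000, burn_in = 1000,
                                           seed = 75))
  zeros <- mfrm_params(rep(0, 30), rep(0, 5), rep(0, 5), rep(0, 5))
  expect_lt(compute_error(fit$estimates, truth, scope = "ability"),
            compute_error(zeros, truth, scope = "ability"))
  expect_identical(fit$estimates$gamma[1], 0)
})

test_that("anchored estimation sharpens with data volume", {
  # paired design: one truth and one complete dataset per seed at J = 100,
  # re-estimated from nested examinee subsets so only the data volume varies
  per_seed <- purrr::map(1:4, function(s) {
    set.seed(200 + s)
    base <- generate_parameters(100, 5, 5, 5)
    new <- generate_parameters(100, 5, 5, 5)
    emb <- embed_common(base, new, C_R = 2, C_I = 2)
    dat <- sample_dataset(emb$params)
    mask <- fixed_mask(emb$layout)
    purrr::map_dbl(c(25, 50, 100), function(J) {
      sub <- dat[dat$examinee <= J, ]
      tr <- emb$params; tr$theta <- tr$theta[1:J]; tr$J <- J
      fit <- estimate_eap(sub, J, 5, 5, 5, mask = mask,
                          config = mcmc_config(iterations = 3000,
                                               burn_in = 1200,
                                               seed = 300 + s))
      mean(c(compute_error(fit$estimates, tr, scope = "task", mask = mask),
             compute_error(fit$estimates, tr, scope = "rater", mask = mask)))
    })
  })
  errs <- colMeans(do.call(rbind, per_seed))
  expect_true(all(diff(errs) < 0))
})

test_that("seeded estimation is exactly reproducible and well mixed", {
  inst <- toy_instance(J = 10, I = 3, R = 3, K = 4, seed = 76)
  f1 <- estimate_eap(inst$data, 10, 3, 3, 4, config = quick_mcmc(seed = 77))
  f2 <- estimate_eap(inst$data, 10, 3, 3, 4, config = quick_mcmc(seed = 77))
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$draws, f2$draws)
  g <- glance(f1)
  expect_true(g$accept_theta > 0.1 && g$accept_theta < 0.7)
  expect_equal(g$n_draws, (1200 - 400) / 2)
  # duplicate records are rejected
  dup <- dplyr::bind_rows(inst$data[1, ], inst$data[1, ])
  expect_error(estimate_eap(dup, 10, 3, 3, 4, config = quick_mcmc(1)),
               class = "facetlink_data_error")
})
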