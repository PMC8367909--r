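test_that("error indices reduce deviations as defined", {
  set.seed(81)
  truth <- generate_parameters(10, 4, 4, 5)
  expect_equal(compute_error(truth, truth), 0)
  expect_equal(compute_error(truth, truth, "mae"), 0)
  shifted <- truth
  shifted$theta <- truth$theta + 0.1
  expect_equal(compute_error(shifted, truth, "rmse", "ability"), 0.1)
  expect_equal(compute_error(shifted, truth, "mae", "ability"), 0.1)
  expect_equal(compute_error(shifted, truth, "abs_mean_bias", "ability"), 0.1)
  # alternating +/- 0.1 deviations: bias cancels, rmse does not
  alt <- truth
  alt$theta <- truth$theta + 0.1 * (-1)^(seq_len(10) + 1)
  expect_equal(compute_error(alt, truth, "rmse", "ability"), 0.1)
  expect_equal(compute_error(alt, truth, "abs_mean_bias", "ability"), 0)
  # odd-length alternating tail: |mean| = 0.1 / n
  alt5 <- truth
  alt5$gamma <- truth$gamma + 0.1 * (-1)^(seq_len(4) + 1)
  expect_equal(compute_error(alt5, truth, "abs_mean_bias", "rater"), 0)
  alt3 <- truth
  alt3$beta <- truth$beta + c(0.1, -0.1, 0.1, 0)
  expect_equal(compute_error(alt3, truth, "abs_mean_bias", "task"), 0.1 / 4)
})

test_that("anchored parameters are excluded from the error scope", {
  set.seed(82)
  truth <- generate_parameters(5, 4, 4, 5)
  est <- truth
  est$gamma[2] <- truth$gamma[2] + 5
  est$beta[3] <- truth$beta[3] + 5
  mask <- fixed_mask(gamma_idx = 2L, gamma_val = est$gamma[2],
                     beta_idx = 3L, beta_val = est$beta[3])
  expect_equal(compute_error(est, truth, "rmse", "all_free", mask), 0)
  expect_gt(compute_error(est, truth, "rmse", "all_free"), 0)
  expect_gt(compute_error(est, truth, "rmse", "task", mask,
                          include_anchored = TRUE), 0)
  # scope with nothing free left
  full_mask <- fixed_mask(beta_idx = 1:4, beta_val = truth$beta)
  expect_error(compute_error(truth, truth, "rmse", "task", full_mask),
               class = "facetlink_invalid_scope")
})

test_that("threshold is the calibration mean plus two sample SDs", {
  fake_errors <- c(0.1, 0.2, 0.3)
  local_mocked_bindings(
    run_replication = function(config, C_R, C_I, rep, calibration = FALSE) {
      tibble::tibble(index = "rmse", scope = "all_free",
                     error = fake_errors[rep])
    }
  )
  cfg <- experiment_config(J = 10, I = 3, R = 3, C_R = 1, C_I = 1,
                           replications = 3, seed = 1)
  thr <- compute_threshold(cfg, 1, 1)
  expect_equal(thr$mu, 0.2)
  expect_equal(thr$sigma, 0.1)
  expect_equal(thr$delta, 0.4)
  # all equal errors collapse the threshold onto the common value
  fake_errors <- c(0.15, 0.15, 0.15)
  thr2 <- compute_threshold(cfg, 1, 1)
  expect_equal(thr2$delta, 0.15)
})

test_that("replications are deterministic and stage seeds are distinct", {
  cfg <- experiment_config(J = 20, I = 3, R = 4, C_R = 1, C_I = 1,
                           replications = 2, mcmc = quick_mcmc(), seed = 9)
  a <- run_replication(cfg, 1, 1, 1)
  b <- run_replication(cfg, 1, 1, 1)
  expect_identical(a, b)
  c <- run_replication(cfg, 1, 1, 2)
  expect_false(identical(a$error, c$error))
  # calibration runs form a different stream
  d <- run_replication(cfg, 1, 1, 1, calibration = TRUE)
  expect_false(identical(a$error, d$error))
  # seed derivation is stable and in range
  expect_identical(derive_seed(9, 1, 1, 1, "run-base"),
                   derive_seed(9, 1, 1, 1, "run-base"))
  stages <- c("run-base", "run-new", "run-embed", "run-sample", "run-mcmc",
              "cal-base", "cal-sample")
  seeds <- vapply(stages, function(s) derive_seed(9, 1, 1, 1, s), integer(1))
  expect_equal(anyDuplicated(seeds), 0)
  expect_true(all(seeds >= 1 & seeds <= 2^31 - 1))
})

test_that("a one-cell grid composes replication and threshold outputs", {
  cfg <- experiment_config(J = 20, I = 4, R = 4, C_R = 1, C_I = 2,
                           replications = 3, mcmc = quick_mcmc(), seed = 11)
  rep_errs <- purrr::map_dbl(1:3, ~ run_replication(cfg, 1, 2, .x)$error)
  thr <- compute_threshold(cfg, 1, 2)
  grid <- run_grid(cfg)
  expect_equal(nrow(grid), 1)
  expect_equal(grid$mean_error, mean(rep_errs))
  expect_equal(grid$delta, thr$delta)
  expect_identical(grid$pass, grid$mean_error < grid$delta)
  expect_equal(grid$n_reps, 3)
  # identical master seed -> identical report
  expect_equal(tibble::as_tibble(run_grid(cfg)), tibble::as_tibble(grid))
  # report utilities
  lines <- format_grid(grid)
  expect_match(lines[2], "C_I=2")
  expect_s3_class(autoplot(grid), "ggplot")
  expect_error(experiment_config(J = 10, I = 3, R = 3, replications = 1),
               class = "facetlink_config_error")
  expect_error(experiment_config(J = 10, I = 3, R = 3, C_R = 5),
               class = "facetlink_config_error")
})
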