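test_that("generated category parameters are sorted, centered, and pinned", {
  set.seed(61)
  for (rep in 1:20) {
    p <- generate_parameters(J = 3, I = 2, R = 2, K = 5)
    expect_identical(p$d[1], 0)
    expect_true(all(diff(p$d[2:5]) >= 0))
    expect_lt(abs(sum(p$d[2:5])), 1e-12)
  }
  p2 <- generate_parameters(J = 2, I = 2, R = 2, K = 2)
  expect_identical(p2$d, c(0, 0))
})

test_that("generation is reproducible bit-for-bit and respects the spec", {
  set.seed(62); a <- generate_parameters(50, 5, 5, 5, scenario_spec(3))
  set.seed(62); b <- generate_parameters(50, 5, 5, 5, scenario_spec(3))
  expect_identical(a, b)
  # large-sample moments match the configured distribution within 3 SEs
  set.seed(63)
  big <- generate_parameters(J = 1e5, I = 2, R = 2, K = 5,
                             spec = distribution_spec(theta_mean = -0.5))
  expect_lt(abs(mean(big$theta) + 0.5), 3 / sqrt(1e5))
  expect_lt(abs(sd(big$theta) - 1), 3 / sqrt(2 * 1e5))
})

test_that("shift scenarios move exactly the intended class means", {
  s1 <- scenario_spec(1); s2 <- scenario_spec(2)
  s3 <- scenario_spec(3); s4 <- scenario_spec(4)
  get <- function(s, cls) s$mean[s$class == cls]
  expect_equal(get(s1, "theta"), -0.5); expect_equal(get(s1, "beta"), 0)
  expect_equal(get(s2, "theta"), -0.2)
  expect_equal(get(s3, "beta"), 0.5); expect_equal(get(s3, "gamma"), 0)
  expect_equal(get(s4, "gamma"), 0.5); expect_equal(get(s4, "beta"), 0)
  expect_true(all(s1$sd == 1))
  expect_error(distribution_spec(theta_sd = 0), class = "facetlink_config_error")
  expect_error(scenario_spec(5), class = "facetlink_config_error")
})

test_that("embedding replaces exactly the selected slots with base values", {
  set.seed(64)
  base <- generate_parameters(30, 6, 7, 5)
  new <- generate_parameters(30, 6, 7, 5, scenario_spec(1))
  none <- embed_common(base, new, 0, 0)
  expect_identical(none$params, new)
  expect_equal(none$layout$C_R, 0)
  full <- embed_common(base, new, C_R = 7, C_I = 6)
  expect_setequal(full$params$gamma, base$gamma)
  expect_setequal(full$params$beta, base$beta)
  emb <- embed_common(base, new, C_R = 2, C_I = 3)
  moved_g <- which(emb$params$gamma != new$gamma)
  moved_b <- which(emb$params$beta != new$beta)
  expect_setequal(moved_g, emb$layout$common_raters$new)
  expect_setequal(moved_b, emb$layout$common_tasks$new)
  expect_equal(emb$params$gamma[emb$layout$common_raters$new],
               base$gamma[emb$layout$common_raters$base])
  expect_identical(emb$params$theta, new$theta)
  expect_identical(emb$params$d, new$d)
  expect_error(embed_common(base, new, C_R = 8, C_I = 0),
               class = "facetlink_invalid_layout")
})

test_that("drift touches the prescribed number of commons and nothing else", {
  set.seed(65)
  base <- generate_parameters(20, 8, 9, 5)
  new <- generate_parameters(20, 8, 9, 5, scenario_spec(1))
  count_drift <- function(C_R, C_I) {
    emb <- embed_common(base, new, C_R, C_I)
    dr <- inject_drift(emb$params, emb$layout)
    c(raters = sum(dr$gamma != emb$params$gamma),
      tasks = sum(dr$beta != emb$params$beta))
  }
  expect_equal(count_drift(1, 1), c(raters = 0, tasks = 1))
  expect_equal(count_drift(5, 3), c(raters = 2, tasks = 2))
  expect_equal(count_drift(3, 4), c(raters = 1, tasks = 2))
  # drifted entries are commons; theta and d are untouched bit-for-bit
  emb <- embed_common(base, new, 4, 4)
  dr <- inject_drift(emb$params, emb$layout)
  expect_true(all(which(dr$gamma != emb$params$gamma) %in%
                    emb$layout$common_raters$new))
  expect_true(all(which(dr$beta != emb$params$beta) %in%
                    emb$layout$common_tasks$new))
  expect_identical(dr$theta, emb$params$theta)
  expect_identical(dr$d, emb$params$d)
})

test_that("sampled datasets cover exactly the assigned triples, reproducibly", {
  set.seed(66)
  p <- generate_parameters(2, 2, 2, 4)
  full <- sample_dataset(p)
  expect_equal(nrow(full), 8)
  expect_true(all(full$score %in% 1:4))
  set.seed(67); a <- sample_dataset(p)
  set.seed(67); b <- sample_dataset(p)
  expect_identical(a, b)
  pm <- generate_parameters(100, 10, 10, 5)
  dat <- sample_dataset(pm, build_design(100, 10, 10, 2))
  expect_equal(nrow(dat), 2000)
  expect_error(sample_dataset(p, build_design(3, 2, 2, 2)),
               class = "facetlink_data_error")
})
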