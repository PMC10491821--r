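test_that("parameter draws stay inside the confidence box with uniform mean", {
  draws <- sample_ci_params(naive_m, n = 1e5, seed = 1)
  expect_true(all(draws$meanlog >= 5.44 & draws$meanlog <= 5.94))
  expect_true(all(draws$sdlog >= 0.35 & draws$sdlog <= 0.69))
  expect_lt(abs(mean(draws$meanlog) - (5.44 + 5.94) / 2), 0.01)
  expect_lt(abs(mean(draws$sdlog) - (0.35 + 0.69) / 2), 0.01)
  # fit without intervals: always the point estimate
  pt <- sample_ci_params(point_fit(naive_m), n = 10, seed = 1)
  expect_true(all(pt$meanlog == 5.69 & pt$sdlog == 0.53))
})

test_that("Monte Carlo tallies are conserved and percentages bounded", {
  rep1 <- run_misid(naive_f, naive_m, solve_thresholds(naive_f, naive_m, 0.95),
                    n_reps_per_sex = 5000, seed = 1)
  sums <- rowSums(rep1$counts[, c("assigned_F", "assigned_M", "assigned_U")])
  expect_equal(unname(sums), c(5000, 5000))
  gl <- glance(rep1)
  pcts <- c(gl$pct_misidentified_f, gl$pct_misidentified_m, gl$pct_unknown)
  expect_true(all(pcts >= 0 & pcts <= 100))
  # identical seed, identical report
  rep2 <- run_misid(naive_f, naive_m, solve_thresholds(naive_f, naive_m, 0.95),
                    n_reps_per_sex = 5000, seed = 1)
  expect_identical(glance(rep1), glance(rep2))
})

test_that("indistinguishable sexes are misidentified half the time", {
  fit <- point_fit(naive_f)
  t50 <- new_threshold_set_for_test(exp(2.46))
  rep0 <- run_misid(fit, fit, t50, n_reps_per_sex = 20000, seed = 4)
  expect_lt(abs(rep0$pct_misidentified_f - 50), 1.5)
  expect_lt(abs(rep0$pct_misidentified_m - 50), 1.5)
})

test_that("zero-uncertainty Monte Carlo converges to the closed form", {
  t50c <- solve_thresholds(chal_f, chal_m, 0.5)  # 129.7
  oracle <- misid_closed_form(point_fit(chal_f), point_fit(chal_m), t50c)
  # analytic tails: 1 - Phi((ln 129.7 - 3.45)/0.68), Phi((ln 129.7 - 6.54)/0.85)
  expect_equal(oracle$pct_misidentified_f,
               100 * (1 - pnorm((log(129.7) - 3.45) / 0.68)), tolerance = 1e-10)
  expect_equal(oracle$pct_misidentified_m,
               100 * pnorm((log(129.7) - 6.54) / 0.85), tolerance = 1e-10)
  mc <- run_misid(point_fit(chal_f), point_fit(chal_m), t50c,
                  n_reps_per_sex = 1e5, seed = 2)
  se_f <- 100 * sqrt(oracle$pct_misidentified_f / 100 *
                     (1 - oracle$pct_misidentified_f / 100) / 1e5)
  se_m <- 100 * sqrt(oracle$pct_misidentified_m / 100 *
                     (1 - oracle$pct_misidentified_m / 100) / 1e5)
  expect_lt(abs(mc$pct_misidentified_f - oracle$pct_misidentified_f), 3 * se_f)
  expect_lt(abs(mc$pct_misidentified_m - oracle$pct_misidentified_m), 3 * se_m)
})

test_that("closed form is symmetric and degenerates correctly", {
  t50c <- solve_thresholds(chal_f, chal_m, 0.5)
  a <- misid_closed_form(chal_f, chal_m, t50c)
  # swapping the fits while the decision regions stay put complements each
  # rate: what was a correct male call becomes a female misidentification
  b <- misid_closed_form(chal_m, chal_f, t50c)
  expect_equal(b$pct_misidentified_f, 100 - a$pct_misidentified_m)
  expect_equal(b$pct_misidentified_m, 100 - a$pct_misidentified_f)
  # thresholds at +-infinity: everything unknown, nothing misidentified
  inf_rule <- hatchsex:::new_threshold_set("probabilistic", 0.99,
                                           female_upper = -Inf,
                                           male_lower = Inf)
  z <- misid_closed_form(chal_f, chal_m, inf_rule)
  expect_equal(z$pct_misidentified_f, 0)
  expect_equal(z$pct_misidentified_m, 0)
  expect_equal(z$pct_unknown, 100)
})

test_that("raising certainty does not raise misidentification", {
  rates <- purrr::map_dfr(c(0.5, 0.8, 0.95), function(cl) {
    r <- run_misid(chal_f, chal_m, solve_thresholds(chal_f, chal_m, cl),
                   n_reps_per_sex = 1e5, seed = 7)
    tibble::tibble(cl = cl, f = r$pct_misidentified_f,
                   m = r$pct_misidentified_m)
  })
  expect_true(all(diff(rates$f) <= 0))
  expect_true(all(diff(rates$m) <= 0))
})

test_that("adaptive per-replicate thresholds run and stay conserved", {
  r <- run_misid(chal_f, chal_m, solve_thresholds(chal_f, chal_m, 0.8),
                 n_reps_per_sex = 2000, seed = 5, adaptive = TRUE)
  sums <- rowSums(r$counts[, c("assigned_F", "assigned_M", "assigned_U")])
  expect_equal(unname(sums), c(2000, 2000))
  expect_error(run_misid(chal_f, chal_m,
                         empirical_rule(c(15.6, 139), c(114.8, 3773.9)),
                         n_reps_per_sex = 200, seed = 1, adaptive = TRUE),
               class = "hatchsex_config_error")
})

test_that("the F:M proportion test matches its chi-square form", {
  even <- proportion_test(5000, 5000)
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  skewed <- proportion_test(8920, 9185)
  expect_equal(skewed$statistic, 3.85, tolerance = 0.01)
  expect_equal(skewed$p_value, 0.0497, tolerance = 0.01)
  expect_lt(proportion_test(0, 100)$p_value, 1e-20)
  expect_error(proportion_test(0, 0), class = "hatchsex_insufficient_data")
})
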