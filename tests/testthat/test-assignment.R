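test_that("relative probability of male behaves like a density ratio", {
  # identical fits: exactly 1/2 everywhere
  expect_equal(relative_prob_male(c(1, 10, 100), naive_f, naive_f),
               rep(0.5, 3))
  # near the published naive crossing
  expect_lt(abs(relative_prob_male(37.7, naive_f, naive_m) - 0.5), 0.02)
  # deep in each tail the log-density ratio dominates
  expect_lt(relative_prob_male(10, naive_f, naive_m), 1e-8)
  expect_gt(relative_prob_male(100, naive_f, naive_m), 1 - 1e-10)
  expect_error(relative_prob_male(-1, naive_f, naive_m),
               class = "hatchsex_domain_error")
})

test_that("solved thresholds reproduce the published table and snap to grid", {
  t95 <- solve_thresholds(naive_f, naive_m, 0.95)
  expect_equal(t95$female_upper, 32.7)
  expect_equal(t95$male_lower, 43.2)
  t80c <- solve_thresholds(chal_f, chal_m, 0.80)
  expect_equal(t80c$female_upper, 99.7)
  expect_equal(t80c$male_lower, 167.1)
  # 50% certainty collapses to a single grid value at the crossing
  t50 <- solve_thresholds(naive_f, naive_m, 0.5)
  expect_equal(t50$female_upper, t50$male_lower)
  expect_equal(t50$female_upper, 37.7)
  # equal-sigma case: crossing at the lognormal-symmetric midpoint e^1
  f0 <- make_lnorm_fit(0, 1); m2 <- make_lnorm_fit(2, 1)
  teq <- solve_thresholds(f0, m2, 0.5, search_range = c(0.5, 100))
  expect_equal(teq$female_upper, exp(1), tolerance = 0.05)
})

test_that("threshold bands nest as certainty rises", {
  certs <- c(0.5, 0.8, 0.95, 0.9999)
  tab <- threshold_table(naive_f, naive_m, certainty = certs)
  expect_true(all(diff(tab$female_upper) <= 0))
  expect_true(all(diff(tab$male_lower) >= 0))
  tabc <- threshold_table(chal_f, chal_m, certainty = certs)
  expect_true(all(diff(tabc$female_upper) <= 0))
  expect_true(all(diff(tabc$male_lower) >= 0))
})

test_that("only the crossing between the modes is used", {
  # below ~0.23 pg/mL the wider male density re-dominates ...
  expect_gt(relative_prob_male(0.1, naive_f, naive_m), 0.5)
  # ... yet the solver pins the decision threshold at the upper crossing
  expect_equal(solve_thresholds(naive_f, naive_m, 0.5)$female_upper, 37.7)
  # reversed orientation is refused
  expect_error(solve_thresholds(naive_m, naive_f, 0.5),
               class = "hatchsex_orientation_error")
})

test_that("probabilistic assignment respects inclusive boundaries", {
  t95 <- solve_thresholds(naive_f, naive_m, 0.95)  # (32.7, 43.2)
  out <- assign_sex(c(30, 37, 32.7, 43.2, 100), t95)
  expect_equal(out$assigned, c("F", "U", "F", "M", "M"))
})

test_that("empirical range rule covers separated and overlapping panels", {
  # naive panels are separated: inclusive extrema bounds
  er <- empirical_rule(female = c(7.8, 20.8), male = c(125.4, 651.4))
  expect_equal(er$female_upper, 20.8)
  expect_equal(er$male_lower, 125.4)
  out <- assign_sex(c(15, 50, 125.4, 20.8), er)
  expect_equal(out$assigned, c("F", "U", "M", "F"))

  # challenged panels overlap between 114.8 and 139.0: strict rule leaves
  # the overlap unknown and reports bounds one grid step inside
  ero <- empirical_rule(female = c(15.6, 139.0), male = c(114.8, 3773.9))
  expect_equal(ero$female_upper, 114.7)
  expect_equal(ero$male_lower, 139.1)
  expect_equal(assign_sex(c(100, 120, 200), ero)$assigned, c("F", "U", "M"))

  # alternative: first observations outside the overlap become the bounds
  f_obs <- c(15.6, 22.8, 68.1, 139.0)
  m_obs <- c(114.8, 198.1, 700.3, 3773.9)
  ero2 <- empirical_rule(f_obs, m_obs, overlap = "exclude_overlap")
  expect_equal(ero2$female_upper, 68.1)
  expect_equal(ero2$male_lower, 198.1)
})

test_that("continuous assignment is a seeded weighted coin with no unknowns", {
  rule <- continuous_rule(naive_f, naive_m)
  # p = 1 far above both modes
  expect_true(all(assign_sex(rep(5000, 20), rule, seed = 1)$assigned == "M"))
  # p ~ 0 at 10 pg/mL
  out <- assign_sex(rep(10, 2000), rule, seed = 2)
  expect_true(all(out$assigned == "F"))
  # identical fits: fair coin
  fair <- assign_sex(rep(50, 10000), continuous_rule(naive_f, naive_f), seed = 3)
  expect_lt(abs(mean(fair$assigned == "M") - 0.5), 0.01)
  expect_false(any(fair$assigned == "U"))
  # reproducible under a fixed seed
  expect_identical(assign_sex(c(40, 41), rule, seed = 9),
                   assign_sex(c(40, 41), rule, seed = 9))
})
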