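test_that("noiseless 4PL data round-trips through the fit", {
  plate <- simulate_plate(params = c(b = 1.3, c = 5, d = 95, e = 40))
  fit <- fit_4pl(plate)
  expect_equal(fit$b, 1.3, tolerance = 1e-4)
  expect_equal(fit$c, 5, tolerance = 1e-3)
  expect_equal(fit$d, 95, tolerance = 1e-3)
  expect_equal(fit$e, 40, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)
  # fitted response at e is the asymptote midpoint
  expect_equal(predict_4pl(fit, fit$e), (fit$c + fit$d) / 2, tolerance = 1e-8)
})

test_that("4PL fitting is scale-equivariant in concentration", {
  plate <- simulate_plate(noise_sd = 2, seed = 8)
  f1 <- fit_4pl(plate)
  f2 <- fit_4pl(dplyr::mutate(plate, concentration = concentration * 10))
  expect_equal(f2$e, 10 * f1$e, tolerance = 1e-5)
  expect_equal(f2$b, f1$b, tolerance = 1e-5)
  expect_equal(f2$c, f1$c, tolerance = 1e-4)
  expect_equal(f2$d, f1$d, tolerance = 1e-4)
})

test_that("ED50 is recovered within 15% under realistic noise", {
  err <- vapply(1:200, function(s) {
    plate <- simulate_plate(params = c(b = 1, c = 0, d = 100, e = 50),
                            noise_sd = 2, dilution_steps = 8,
                            duplicates = 2, seed = s)
    abs(fit_4pl(plate)$e / 50 - 1)
  }, 0)
  expect_lt(stats::quantile(err, 0.9), 0.15)
})

test_that("too-sparse dilution series are rejected", {
  plate <- simulate_plate(dilution_steps = 4)
  expect_error(fit_4pl(plate), class = "hatchsex_insufficient_data")
})

test_that("inverse prediction inverts the fitted curve exactly", {
  fit <- fit_4pl(simulate_plate(params = c(b = 1, c = 0, d = 100, e = 50)))
  # algebraic case: 20 = 100/(1 + x/50) at x = 200
  expect_equal(invert_4pl(fit, 20), 200, tolerance = 1e-4)
  expect_equal(invert_4pl(fit, (fit$c + fit$d) / 2), fit$e, tolerance = 1e-8)
  set.seed(9)
  y <- runif(100, fit$c + 1, fit$d - 1)
  expect_equal(predict_4pl(fit, invert_4pl(fit, y)), y, tolerance = 1e-6)
  expect_error(invert_4pl(fit, 101), class = "hatchsex_out_of_range")
})

test_that("parallel curves from the same 4PL are not rejected", {
  std <- simulate_plate(noise_sd = 0, seed = 1)
  pool <- simulate_plate(noise_sd = 0, seed = 2, series_id = "pooled")
  res <- parallelism_lrt(std, pool)
  full <- res[res$model == "full", ]
  expect_equal(full$df, 2L)
  expect_lt(full$chi2, 1e-6)
  expect_gt(full$p_value, 0.99)
  # statistic is non-negative for every nested comparison
  expect_true(all(res$chi2[res$model != "reduced"] >= 0))
})

test_that("a doubled slope in the sample series is detected", {
  std <- simulate_plate(params = c(b = 1, c = 0, d = 100, e = 50),
                        noise_sd = 2, seed = 3)
  steep <- simulate_plate(params = c(b = 2, c = 0, d = 100, e = 50),
                          noise_sd = 2, seed = 4, series_id = "pooled")
  res <- parallelism_lrt(std, steep)
  expect_lt(res$p_value[res$model == "full"], 0.01)
})

test_that("QC windows, duplicate CV and rerun flags follow the assay rules", {
  r <- qc_evaluate(replicates = c(90, 110))
  expect_equal(r$dup_cv, 100 * sd(c(90, 110)) / 100, tolerance = 1e-10)
  expect_lt(r$dup_cv, 20)  # CV itself does not force a rerun
  # below the permissive floor
  low <- qc_evaluate(bb0 = 9.91)
  expect_false(low$bb0_permissive_pass)
  expect_false(low$bb0_strict_pass)
  expect_true(low$rerun_flag)
  # strict pass implies permissive pass across the response range
  for (b in c(5, 15, 20, 50, 80, 85, 95)) {
    q <- qc_evaluate(bb0 = b)
    expect_true(!q$bb0_strict_pass || q$bb0_permissive_pass)
  }
  # single replicate: CV 0, flag driven by the window only
  single <- qc_evaluate(replicates = 50)
  expect_equal(single$dup_cv, 0)
  expect_false(single$rerun_flag)
  expect_error(qc_evaluate(replicates = c(-1, 1)),
               class = "hatchsex_domain_error")
})

test_that("intra- and interplate CVs summarise a shared control", {
  plates <- tibble::tibble(
    plate_id = rep(c("p1", "p2"), each = 2),
    series_id = "control",
    response_bb0 = c(100, 100, 120, 120))
  out <- plate_cvs(plates)
  expect_equal(out$intraplate_mean_cv, 0)
  expect_equal(out$interplate_cv, 100 * sd(c(100, 120)) / 110,
               tolerance = 1e-10)
  expect_error(plate_cvs(plates[plates$plate_id == "p1", ]),
               class = "hatchsex_insufficient_data")
})
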