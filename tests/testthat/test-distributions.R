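test_that("lognormal MLE equals the normal MLE of the log values", {
  set.seed(42)
  x <- rlnorm(200, 3, 0.7)
  fit <- fit_hormone_dist(x)
  lx <- log(x)
  expect_equal(fit$estimate[["meanlog"]], mean(lx))
  # divisor-n MLE, not the n-1 sample SD
  expect_equal(fit$estimate[["sdlog"]], sqrt(mean((lx - mean(lx))^2)))
  expect_false(isTRUE(all.equal(fit$estimate[["sdlog"]], sd(lx))))
  # independent cross-check against the standard fitting tool
  ref <- fitdistrplus::fitdist(x, "lnorm")
  expect_equal(unname(fit$estimate), unname(ref$estimate), tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(fit_hormone_dist(rep(exp(2), 3)),
               class = "hatchsex_degenerate_data")
  expect_error(fit_hormone_dist(c(exp(1), exp(3))),
               class = "hatchsex_insufficient_data")
  expect_error(fit_hormone_dist(c(1, 2, -3)), class = "hatchsex_domain_error")
})

test_that("parameters are recovered from large samples", {
  set.seed(7)
  x <- rlnorm(5000, 5.69, 0.53)
  fit <- fit_hormone_dist(x)
  expect_lt(abs(fit$estimate[["meanlog"]] - 5.69), 0.03)
  expect_lt(abs(fit$estimate[["sdlog"]] - 0.53), 0.03)
  # fitted lognormal mean matches the analytic exp(mu + sigma^2/2)
  m <- fit$estimate[["meanlog"]]; s <- fit$estimate[["sdlog"]]
  expect_equal(exp(m + s^2 / 2), mean(x), tolerance = 0.05)
})

test_that("bootstrap CIs are deterministic, ordered and shrink to a point", {
  set.seed(3)
  x <- rlnorm(60, 2.46, 0.29)
  f1 <- bootstrap_ci(fit_hormone_dist(x), n_boot = 500, seed = 10)
  f2 <- bootstrap_ci(fit_hormone_dist(x), n_boot = 500, seed = 10)
  expect_identical(f1$ci, f2$ci)
  for (p in c("meanlog", "sdlog")) {
    expect_lte(f1$ci[[p]][1], f1$estimate[[p]])
    expect_gte(f1$ci[[p]][2], f1$estimate[[p]])
  }
  # nearly-identical data: CI width collapses towards zero
  y <- rep(c(10, 10.0001, 9.9999), 20)
  fy <- bootstrap_ci(fit_hormone_dist(y), n_boot = 300, seed = 1)
  expect_lt(diff(fy$ci$meanlog), 1e-4)
})

test_that("K-S statistic matches closed-form and enumerated oracles", {
  fit <- make_lnorm_fit(2, 0.5)
  # single observation at the fitted median: D = 0.5
  expect_equal(ks_gof(fit, data = exp(2))$statistic, 0.5)
  # sample at fitted quantiles i/(n+1), n = 9: sup|F_hat - F| = 0.1
  q <- qlnorm((1:9) / 10, 2, 0.5)
  expect_equal(ks_gof(fit, data = q)$statistic, 0.1, tolerance = 1e-12)
  expect_error(ks_gof(fit, data = numeric(0)),
               class = "hatchsex_insufficient_data")
})

test_that("K-S test against the generating distribution is calibrated", {
  pvals <- vapply(1:100, function(s) {
    set.seed(s)
    ks_gof(make_lnorm_fit(5.69, 0.53), data = rlnorm(1000, 5.69, 0.53))$p_value
  }, 0)
  expect_gte(mean(pvals > 0.01), 0.98)
})

test_that("diagnostics pair empirical and theoretical quantiles", {
  set.seed(1)
  x <- rlnorm(40, 3, 0.4)
  fit <- fit_hormone_dist(x)
  d <- dist_diagnostics(fit)
  expect_equal(nrow(d), 40)
  expect_true(all(diff(d$theoretical) > 0))
  expect_equal(d$empirical, sort(x))
  # perfect-fit input: empirical quantiles equal theoretical ones
  q <- qlnorm((1:19) / 20, 3, 0.4)
  dq <- dist_diagnostics(make_lnorm_fit(3, 0.4), data = q)
  expect_equal(dq$empirical, dq$theoretical, tolerance = 1e-10)
})

test_that("lognormal beats gamma on heavy-tailed male-panel-sized samples", {
  # gamma is close enough to win individual small samples at times, but
  # the expected log-likelihood advantage of the generating family is
  # positive, and the lognormal fit never fails where gamma can
  diffs <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rlnorm(18, 5.69, 0.85)
    ln <- fit_hormone_dist(x, "lognormal")
    gm <- tryCatch(fit_hormone_dist(x, "gamma"), error = function(e) NULL)
    if (is.null(gm)) NA_real_ else ln$loglik - gm$loglik
  }, 0)
  expect_gt(mean(diffs, na.rm = TRUE), 0)
  expect_gt(mean(diffs > 0, na.rm = TRUE), 0.5)
})

test_that("gamma and weibull families fit through the standard MLE engine", {
  set.seed(5)
  x <- rgamma(300, shape = 4, rate = 0.5)
  fg <- fit_hormone_dist(x, "gamma")
  expect_named(fg$estimate, c("shape", "rate"))
  expect_lt(abs(fg$estimate[["shape"]] - 4), 1)
  fw <- fit_hormone_dist(x, "weibull")
  expect_named(fw$estimate, c("shape", "scale"))
  expect_gt(fg$loglik, -Inf)
})

test_that("tidy and glance expose estimates, intervals and fit metadata", {
  set.seed(2)
  fit <- bootstrap_ci(fit_hormone_dist(rlnorm(50, 2.5, 0.3)),
                      n_boot = 200, seed = 1)
  td <- tidy(fit)
  expect_equal(td$term, c("meanlog", "sdlog"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n, 50)
  expect_equal(gl$boot_iterations, 200L)
})
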