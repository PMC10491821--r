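#' Fitted parametric distribution for a hormone concentration sample
#'
#' @description
#' `fit_hormone_dist()` fits a right-skewed parametric family to positive
#' concentration values (pg/mL) by maximum likelihood. The lognormal fit is
#' closed form: `meanlog` is the mean of the log values and `sdlog` the
#' root mean squared deviation of the logs (divisor `n`, the true MLE);
#' gamma and Weibull fits are delegated to
#' [fitdistrplus::fitdist()]. The result is a `hormone_fit` object that
#' downstream threshold and simulation functions consume.
#'
#' Input can be a bare numeric vector or a data frame holding a
#' `testosterone_pg_ml` column (the sample-record schema used throughout
#' the package), so grouped fits chain naturally with dplyr.
#'
#' @param x Numeric vector of concentrations (pg/mL), or a data frame with
#'   a `testosterone_pg_ml` column.
#' @param family One of `"lognormal"`, `"gamma"`, `"weibull"`.
#' @param label Optional character tag (e.g. `"naive_female"`) carried in
#'   printed and tidied output.
#' @return A `hormone_fit`: list with elements `family`, `estimate` (named
#'   parameter vector), `n`, `loglik`, `data`, and (after
#'   [bootstrap_ci()] / [ks_gof()]) `ci`, `boot`, `ks`.
#' @export
#' @examples
#' x <- simulate_known_sex(generator_config(n_female = 30, n_male = 0, seed = 1))
#' fit_hormone_dist(x, family = "lognormal")
fit_hormone_dist <- function(x, family = c("lognormal", "gamma", "weibull"),
                             label = NULL) {
  family <- match.arg(family)
  x <- extract_conc(x)
  if (length(x) < 3) {
    abort("need at least 3 observations to fit a distribution",
          class = "hatchsex_insufficient_data")
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("all concentrations must be finite and > 0",
          class = "hatchsex_domain_error")
  }
  est <- fit_mle_params(x, family)
  new_hormone_fit(
    family = family, estimate = est$estimate, n = length(x),
    loglik = est$loglik, data = x, label = label
  )
}

# Core MLE; shared by the user-facing fit and the bootstrap refits.
fit_mle_params <- function(x, family) {
  if (family == "lognormal") {
    lx <- log(x)
    m <- mean(lx)
    s <- sqrt(mean((lx - m)^2))
    if (s == 0) {
      abort("degenerate sample: zero variance on the log scale",
            class = "hatchsex_degenerate_data")
    }
    list(estimate = c(meanlog = m, sdlog = s),
         loglik = sum(dlnorm(x, m, s, log = TRUE)))
  } else {
    if (sd(x) == 0) {
      abort("degenerate sample: zero variance",
            class = "hatchsex_degenerate_data")
    }
    dist <- if (family == "gamma") "gamma" else "weibull"
    ft <- fitdistrplus::fitdist(x, dist, method = "mle")
    list(estimate = ft$estimate, loglik = ft$loglik)
  }
}

new_hormone_fit <- function(family, estimate, n, loglik = NA_real_, ci = NULL,
                            boot = NULL, ks = NULL, data = NULL, label = NULL) {
  structure(
    list(family = family, estimate = estimate, n = n, loglik = loglik,
         ci = ci, boot = boot, ks = ks, data = data, label = label),
    class = "hormone_fit"
  )
}

extract_conc <- function(x) {
  if (is.data.frame(x)) {
    if (!"testosterone_pg_ml" %in% names(x)) {
      abort("data frame input must have a `testosterone_pg_ml` column",
            class = "hatchsex_schema_error")
    }
    x <- x$testosterone_pg_ml
  }
  as.numeric(x)
}

#' @export
print.hormone_fit <- function(x, ...) {
  cat(sprintf("<hormone_fit: %s%s, n = %d>\n", x$family,
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"), x$n))
  for (p in names(x$estimate)) {
    ci <- if (!is.null(x$ci)) sprintf(" (95%% CI %.3g-%.3g)", x$ci[[p]][1],
                                      x$ci[[p]][2]) else ""
    cat(sprintf("  %s = %.4g%s\n", p, x$estimate[[p]], ci))
  }
  if (!is.null(x$ks)) {
    cat(sprintf("  K-S D = %.3f, p = %.3f\n", x$ks$statistic, x$ks$p_value))
  }
  invisible(x)
}

# Distribution function dispatch for the three supported families.
fit_pfun <- function(fit) {
  e <- fit$estimate
  switch(fit$family,
    lognormal = function(q) plnorm(q, e[["meanlog"]], e[["sdlog"]]),
    gamma     = function(q) pgamma(q, e[["shape"]], e[["rate"]]),
    weibull   = function(q) pweibull(q, e[["shape"]], e[["scale"]])
  )
}

fit_qfun <- function(fit) {
  e <- fit$estimate
  switch(fit$family,
    lognormal = function(p) qlnorm(p, e[["meanlog"]], e[["sdlog"]]),
    gamma     = function(p) qgamma(p, e[["shape"]], e[["rate"]]),
    weibull   = function(p) qweibull(p, e[["shape"]], e[["scale"]])
  )
}

fit_dfun <- function(fit) {
  e <- fit$estimate
  switch(fit$family,
    lognormal = function(x) dlnorm(x, e[["meanlog"]], e[["sdlog"]]),
    gamma     = function(x) dgamma(x, e[["shape"]], e[["rate"]]),
    weibull   = function(x) dweibull(x, e[["shape"]], e[["scale"]])
  )
}

#' Nonparametric bootstrap confidence intervals for fitted parameters
#'
#' Resamples the fitted sample with replacement, refits the same family,
#' and attaches percentile (2.5%, 97.5% by default) intervals for each
#' parameter to the fit. Refits that fail (e.g. a degenerate resample or a
#' non-converging gamma fit) are dropped and counted; more than 50%
#' failures is an error. Lognormal refits are vectorised and fast even at
#' the conventional 10,000 iterations.
#'
#' @param fit A [hormone_fit] carrying its sample data.
#' @param n_boot Number of bootstrap iterations (>= 100).
#' @param conf_level Confidence level for the percentile interval.
#' @param seed Optional integer seed; identical inputs give identical
#'   interval endpoints.
#' @return The fit, with `ci` (named list of `c(lo, hi)`) and `boot`
#'   (list: `iterations`, `failed`) filled in.
#' @export
#' @examples
#' x <- rlnorm(50, 2.46, 0.29)
#' bootstrap_ci(fit_hormone_dist(x), n_boot = 500, seed = 1)
bootstrap_ci <- function(fit, n_boot = 10000, conf_level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "hormone_fit"))
  if (is.null(fit$data)) {
    abort("fit carries no sample data to resample",
          class = "hatchsex_insufficient_data")
  }
  if (n_boot < 100) abort("n_boot must be >= 100", class = "hatchsex_config_error")
  x <- fit$data
  n <- length(x)
  alpha <- (1 - conf_level) / 2

  boot_est <- with_seed_maybe(seed, {
    if (fit$family == "lognormal") {
      lx <- log(x)
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
      bm <- rowMeans(matrix(lx[idx], nrow = n_boot))
      bs <- sqrt(rowMeans((matrix(lx[idx], nrow = n_boot) - bm)^2))
      cbind(meanlog = bm, sdlog = bs)
    } else {
      reps <- vapply(seq_len(n_boot), function(i) {
        xb <- x[sample.int(n, n, replace = TRUE)]
        tryCatch(fit_mle_params(xb, fit$family)$estimate,
                 error = function(e) rep(NA_real_, length(fit$estimate)))
      }, numeric(length(fit$estimate)))
      t(reps)
    }
  })
  colnames(boot_est) <- names(fit$estimate)
  # degenerate resamples (zero log-scale spread) count as failed refits
  ok <- apply(boot_est, 1, function(r) all(is.finite(r)) && all(r[-1] >= 0))
  if (fit$family == "lognormal") ok <- ok & boot_est[, "sdlog"] > 0
  n_fail <- sum(!ok)
  if (n_fail > n_boot / 2) {
    abort(sprintf("unstable fit: %d of %d bootstrap refits failed", n_fail, n_boot),
          class = "hatchsex_unstable_fit")
  }
  keep <- boot_est[ok, , drop = FALSE]
  fit$ci <- lapply(stats::setNames(names(fit$estimate), names(fit$estimate)),
                   function(p) unname(quantile(keep[, p], c(alpha, 1 - alpha))))
  fit$boot <- list(iterations = n_boot, failed = n_fail,
                   conf_level = conf_level)
  fit
}

#' Kolmogorov-Smirnov goodness of fit for a fitted distribution
#'
#' One-sample two-sided K-S test of the fitted sample against the fitted
#' CDF, with the fitted parameters treated as known (the convention used
#' when reporting D and p alongside the parameter table; the
#' estimated-parameter caveat makes the test conservative).
#'
#' @param fit A [hormone_fit] carrying data, or pass `data` explicitly.
#' @param data Optional numeric vector to test instead of `fit$data`.
#' @return One-row tibble: `statistic` (D), `p_value`, `n`.
#' @export
ks_gof <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "hormone_fit"))
  x <- data %||% fit$data
  if (is.null(x) || length(x) == 0) {
    abort("no sample data to test", class = "hatchsex_insufficient_data")
  }
  if (any(!is.finite(fit$estimate))) {
    abort("fitted parameters must be finite", class = "hatchsex_domain_error")
  }
  kt <- suppressWarnings(ks.test(x, fit_pfun(fit)))
  tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
                 n = length(x))
}

#' Quantile-quantile diagnostics for a fitted distribution
#'
#' Pairs the ordered sample with theoretical quantiles of the fitted
#' distribution at plotting positions `i / (n + 1)`; one row per
#' observation. Feed to a Q-Q or empirical-vs-theoretical CDF plot
#' (see [autoplot.hormone_fit()]).
#'
#' @inheritParams ks_gof
#' @return Tibble with columns `prob`, `empirical`, `theoretical`.
#' @export
dist_diagnostics <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "hormone_fit"))
  x <- data %||% fit$data
  if (is.null(x) || length(x) == 0) {
    abort("no sample data to diagnose", class = "hatchsex_insufficient_data")
  }
  n <- length(x)
  p <- seq_len(n) / (n + 1)
  tibble::tibble(prob = p, empirical = sort(x), theoretical = fit_qfun(fit)(p))
}

#' @exportS3Method generics::tidy
tidy.hormone_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    conf.low = if (is.null(x$ci)) NA_real_ else
      vapply(names(x$estimate), function(p) x$ci[[p]][1], 0),
    conf.high = if (is.null(x$ci)) NA_real_ else
      vapply(names(x$estimate), function(p) x$ci[[p]][2], 0)
  )
}

#' @exportS3Method generics::glance
glance.hormone_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n = x$n,
    logLik = x$loglik,
    ks_statistic = if (is.null(x$ks)) NA_real_ else x$ks$statistic,
    ks_p = if (is.null(x$ks)) NA_real_ else x$ks$p_value,
    boot_iterations = if (is.null(x$boot)) NA_integer_ else
      as.integer(x$boot$iterations)
  )
}
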