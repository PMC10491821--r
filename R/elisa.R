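# Four-parameter logistic on the log-concentration axis:
#   response = c + (d - c) / (1 + exp(b * (ln x - ln e)))
# b: slope at the inflection; c, d: lower/upper asymptotes (%B/B0);
# e: inflection concentration (ED50). For a competitive assay d is the
# zero-dose response and b > 0 gives the decreasing curve.
fourpl <- function(x, b, c, d, e) {
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

check_series <- function(series) {
  series <- tibble::as_tibble(series)
  need <- c("concentration", "response_bb0")
  if (!all(need %in% names(series))) {
    abort("plate series needs `concentration` and `response_bb0` columns",
          class = "hatchsex_schema_error")
  }
  if (any(series$concentration <= 0) || any(!is.finite(series$response_bb0))) {
    abort("concentrations must be > 0 and responses finite",
          class = "hatchsex_domain_error")
  }
  series
}

#' Fit a four-parameter logistic (4PL) dose-response curve
#'
#' @description
#' Least-squares fit of `response = c + (d - c) / (1 + exp(b (ln x - ln
#' e)))` to an ELISA dilution series via Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]). Parameters: `b` slope at the inflection
#' (log-concentration axis), `c`/`d` lower/upper asymptotes (%B/B0), `e`
#' inflection concentration (effective dose 50%). The fit is normalised
#' so `c < d` (the mirrored parameterisation `(-b, d, c)` describes the
#' same curve).
#'
#' @param series Data frame with `concentration` (pg/mL, > 0) and
#'   `response_bb0` (%B/B0); at least 5 distinct concentrations.
#' @return A `fourpl_fit`: coefficients, residual sum of squares `rss`,
#'   well count `n`, and the data.
#' @export
#' @examples
#' plate <- simulate_plate(params = c(b = 1, c = 0, d = 100, e = 50), seed = 1)
#' fit_4pl(plate)
fit_4pl <- function(series) {
  series <- check_series(series)
  x <- series$concentration
  y <- series$response_bb0
  if (length(unique(x)) < 5) {
    abort("need at least 5 distinct concentrations to identify 4 parameters",
          class = "hatchsex_insufficient_data")
  }
  if (stats::cor(log(x), y) > 0) {
    warn("responses increase with concentration; expected a competitive (decreasing) curve")
  }
  start <- list(b = 1, c = min(y), d = max(y),
                le = log(x[which.min(abs(y - (min(y) + max(y)) / 2))]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ c + (d - c) / (1 + exp(b * (log(x) - le))),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(err) {
      abort(paste0("4PL fit failed to converge: ", conditionMessage(err)),
            class = "hatchsex_fit_error")
    })
  cf <- coef(fit)
  b <- cf[["b"]]; cc <- cf[["c"]]; dd <- cf[["d"]]; e <- exp(cf[["le"]])
  if (cc > dd) {  # mirror to the canonical c < d orientation
    tmp <- cc; cc <- dd; dd <- tmp; b <- -b
  }
  structure(
    list(b = b, c = cc, d = dd, e = e,
         rss = sum(resid(fit)^2), n = length(y), data = series),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("<fourpl_fit: n = %d, RSS = %.4g>\n", x$n, x$rss))
  cat(sprintf("  b = %.4g, c = %.4g, d = %.4g, e (ED50) = %.4g\n",
              x$b, x$c, x$d, x$e))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fourpl_fit <- function(x, ...) {
  tibble::tibble(term = c("b", "c", "d", "e"),
                 estimate = c(x$b, x$c, x$d, x$e))
}

#' @exportS3Method generics::glance
glance.fourpl_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, sigma = sqrt(x$rss / x$n))
}

#' Predict the 4PL response at given concentrations
#' @param fit A `fourpl_fit`.
#' @param conc Concentrations, pg/mL.
#' @return Numeric responses (%B/B0).
#' @export
predict_4pl <- function(fit, conc) {
  stopifnot(inherits(fit, "fourpl_fit"))
  fourpl(conc, fit$b, fit$c, fit$d, fit$e)
}

#' Invert a fitted 4PL curve (inverse prediction)
#'
#' Back-calculates the concentration producing a given %B/B0 response:
#' `x = e ((d - y) / (y - c))^(1/b)`. Only responses strictly between the
#' asymptotes are invertible.
#'
#' @param fit A `fourpl_fit`.
#' @param response Response values strictly inside `(c, d)`.
#' @return Concentrations, pg/mL.
#' @export
#' @examples
#' fit <- fit_4pl(simulate_plate(params = c(b = 1, c = 0, d = 100, e = 50)))
#' invert_4pl(fit, 20)  # 200 for the (1, 0, 100, 50) curve
invert_4pl <- function(fit, response) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (any(response <= fit$c) || any(response >= fit$d)) {
    abort("response outside the open asymptote interval (c, d)",
          class = "hatchsex_out_of_range")
  }
  fit$e * ((fit$d - response) / (response - fit$c))^(1 / fit$b)
}

#' Parallelism likelihood-ratio test between two dilution series
#'
#' @description
#' Tests whether a sample dilution curve is parallel to the kit standard
#' curve — the assay-validation criterion for a new matrix or species.
#' Both series share the asymptotes (`c`, `d`); the "full" model lets
#' slope `b` and inflection `e` differ between series while the "reduced"
#' model shares all four parameters. Under a Gaussian error model the
#' likelihood-ratio statistic is `chi2 = n ln(RSS_reduced / RSS_full)`
#' with 2 df; the intermediate models (only `b` free, only `e` free) are
#' reported with 1 df each. A non-significant test supports parallelism.
#'
#' @param standard,pooled Data frames with `concentration` and
#'   `response_bb0` for the standard and sample dilution series.
#' @return A tibble with one row per comparison (`full`, `slope`,
#'   `ed50` vs the shared-parameter model): `chi2`, `df`, `p_value`,
#'   `rss` of the larger model, plus `rss_reduced` as an attribute-free
#'   first-class column via the `reduced` row.
#' @export
#' @examples
#' std <- simulate_plate(seed = 1, noise_sd = 2)
#' pool <- simulate_plate(seed = 2, noise_sd = 2, series_id = "pooled")
#' parallelism_lrt(std, pool)
parallelism_lrt <- function(standard, pooled) {
  standard <- check_series(standard)
  pooled <- check_series(pooled)
  dat <- dplyr::bind_rows(
    dplyr::mutate(standard, g = 0),
    dplyr::mutate(pooled, g = 1))
  x <- dat$concentration
  y <- dat$response_bb0
  g <- dat$g
  n <- length(y)

  base <- fit_4pl(dat)   # propagates fit errors; start values for all models
  if (base$rss < 1e-10 * max(1, mean(y^2))) {
    # the shared curve already fits perfectly; nested models cannot improve
    perfect <- function(model, df) {
      tibble::tibble(model = model, rss = base$rss, df = df, chi2 = 0,
                     p_value = 1)
    }
    return(dplyr::bind_rows(
      perfect("full", 2L), perfect("slope", 1L), perfect("ed50", 1L),
      tibble::tibble(model = "reduced", rss = base$rss, df = 0L,
                     chi2 = NA_real_, p_value = NA_real_)))
  }
  start0 <- list(b = base$b, c = base$c, d = base$d, le = log(base$e))
  fit_model <- function(formula, extra) {
    m <- tryCatch(
      minpack.lm::nlsLM(formula, start = c(start0, extra),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(err) {
        abort(paste0("parallelism model failed to converge: ",
                     conditionMessage(err)),
              class = "hatchsex_fit_error")
      })
    sum(resid(m)^2)
  }
  rss_reduced <- base$rss
  rss_full <- fit_model(
    y ~ c + (d - c) / (1 + exp((b + db * g) * (log(x) - (le + dle * g)))),
    list(db = 0, dle = 0))
  rss_slope <- fit_model(
    y ~ c + (d - c) / (1 + exp((b + db * g) * (log(x) - le))),
    list(db = 0))
  rss_ed50 <- fit_model(
    y ~ c + (d - c) / (1 + exp(b * (log(x) - (le + dle * g)))),
    list(dle = 0))

  lrt <- function(model, rss, df) {
    eps <- 1e-12  # noiseless series: both RSS at optimizer floor
    chi2 <- max(0, n * log((rss_reduced + eps) / (rss + eps)))
    tibble::tibble(model = model, rss = rss, df = df, chi2 = chi2,
                   p_value = pchisq(chi2, df, lower.tail = FALSE))
  }
  dplyr::bind_rows(
    lrt("full", rss_full, 2L),
    lrt("slope", rss_slope, 1L),
    lrt("ed50", rss_ed50, 1L),
    tibble::tibble(model = "reduced", rss = rss_reduced, df = 0L,
                   chi2 = NA_real_, p_value = NA_real_)
  )
}

#' Well-level ELISA quality control
#'
#' Applies the assay acceptance rules to one sample's wells: the strict
#' quantifiable window is 20-80 %B/B0 (linear portion of the standard
#' curve), the permissive window 10-90% (90% being the detection limit);
#' the duplicate coefficient of variation is `100 * sd / mean` (sample
#' SD); a sample is flagged for rerun when the CV exceeds 20% or it falls
#' outside the strict window.
#'
#' @param bb0 The sample's %B/B0 reading (mean of replicates if
#'   `replicates` not given).
#' @param replicates Optional numeric vector of replicate responses used
#'   for the CV (a single replicate gives CV 0).
#' @return One-row tibble: `bb0`, `dup_cv`, `bb0_strict_pass`,
#'   `bb0_permissive_pass`, `rerun_flag`.
#' @export
#' @examples
#' qc_evaluate(replicates = c(90, 110))
qc_evaluate <- function(bb0 = NULL, replicates = NULL) {
  if (is.null(replicates) && is.null(bb0)) {
    abort("supply bb0 and/or replicates", class = "hatchsex_config_error")
  }
  dup_cv <- 0
  if (!is.null(replicates)) {
    m <- mean(replicates)
    if (m == 0) abort("undefined CV: replicate mean is zero",
                      class = "hatchsex_domain_error")
    if (length(replicates) > 1) dup_cv <- 100 * sd(replicates) / m
    bb0 <- bb0 %||% m
  }
  strict <- bb0 >= 20 && bb0 <= 80
  permissive <- bb0 >= 10 && bb0 <= 90
  tibble::tibble(bb0 = bb0, dup_cv = dup_cv,
                 bb0_strict_pass = strict, bb0_permissive_pass = permissive,
                 rerun_flag = dup_cv > 20 || !strict)
}

#' Intra- and interplate coefficients of variation from a shared control
#'
#' A control sample run in replicate on every plate yields two precision
#' summaries: the intraplate CV (per-plate `100 * sd / mean` over the
#' control's replicate wells, averaged across plates) and the interplate
#' CV (`100 * sd / mean` of the per-plate control means).
#'
#' @param plates Data frame with `plate_id`, `series_id`, `response_bb0`.
#' @param control_id Value of `series_id` identifying the control wells.
#' @return One-row tibble: `intraplate_mean_cv`, `interplate_cv`,
#'   `n_plates`.
#' @export
plate_cvs <- function(plates, control_id = "control") {
  plates <- tibble::as_tibble(plates)
  ctl <- plates[plates$series_id == control_id, ]
  if (nrow(ctl) == 0 || length(unique(ctl$plate_id)) < 2) {
    abort("control must be present on at least 2 plates",
          class = "hatchsex_insufficient_data")
  }
  per_plate <- dplyr::summarise(
    dplyr::group_by(ctl, .data$plate_id),
    m = mean(.data$response_bb0),
    cv = if (dplyr::n() > 1) 100 * sd(.data$response_bb0) / mean(.data$response_bb0) else 0,
    .groups = "drop")
  tibble::tibble(
    intraplate_mean_cv = mean(per_plate$cv),
    interplate_cv = 100 * sd(per_plate$m) / mean(per_plate$m),
    n_plates = nrow(per_plate)
  )
}
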