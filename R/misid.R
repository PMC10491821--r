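#' Draw lognormal parameters uniformly within bootstrap confidence intervals
#'
#' The Monte Carlo misidentification engine propagates parameter
#' uncertainty by drawing `meanlog` and `sdlog` independently and
#' uniformly within their 95% bootstrap confidence intervals. A fit
#' without intervals (or with zero-width intervals) yields its point
#' estimates.
#'
#' @param fit A [hormone_fit] (lognormal), ideally after [bootstrap_ci()].
#' @param n Number of parameter draws.
#' @param seed Optional seed.
#' @return Tibble with `n` rows and columns `meanlog`, `sdlog`.
#' @export
sample_ci_params <- function(fit, n = 1, seed = NULL) {
  stopifnot(inherits(fit, "hormone_fit"))
  ci <- fit$ci
  if (is.null(ci)) {
    ci <- list(meanlog = rep(fit$estimate[["meanlog"]], 2),
               sdlog = rep(fit$estimate[["sdlog"]], 2))
  }
  for (p in c("meanlog", "sdlog")) {
    if (any(!is.finite(ci[[p]])) || ci[[p]][1] > ci[[p]][2]) {
      abort("confidence bounds must be finite with lo <= hi",
            class = "hatchsex_config_error")
    }
  }
  with_seed_maybe(seed, tibble::tibble(
    meanlog = runif(n, ci$meanlog[1], ci$meanlog[2]),
    sdlog = runif(n, ci$sdlog[1], ci$sdlog[2])
  ))
}

#' Monte Carlo misidentification rates for a sexing rule
#'
#' @description
#' Estimates how often a sexing rule misidentifies true females and true
#' males. Each replicate (1) draws lognormal parameters for the true sex
#' uniformly within the fit's 95% bootstrap confidence intervals, (2)
#' draws a single concentration from that lognormal, and (3) assigns a
#' sex with the supplied rule. Unknown assignments are excluded from the
#' misidentification denominators. A chi-square proportion test (Yates
#' continuity correction) checks the assigned F:M split across all
#' replicates against 50:50.
#'
#' By default the rule's thresholds stay fixed at the values computed
#' from the point-estimate fits while generation uses the CI-sampled
#' parameters. With `adaptive = TRUE` (probabilistic and continuous rules
#' only) the decision rule is recomputed per replicate from a fresh pair
#' of CI-sampled female and male parameters, using the pointwise density
#' ratio; the two variants bracket the ambiguity in how threshold and
#' generation uncertainty can be linked.
#'
#' @param fit_f,fit_m Lognormal [hormone_fit]s with (optionally) CIs.
#' @param rule A `threshold_set`, [empirical_rule()] or
#'   [continuous_rule()].
#' @param n_reps_per_sex Replicates per true sex (default 10,000).
#' @param seed Optional seed; replicate order is all-female then
#'   all-male.
#' @param adaptive Recompute the rule per replicate from CI-sampled
#'   parameters (see Description).
#' @return A `misid_report`; see [tidy.misid_report()] /
#'   [glance.misid_report()].
#' @export
#' @examples
#' ff <- reference_fit("F", "naive"); fm <- reference_fit("M", "naive")
#' run_misid(ff, fm, solve_thresholds(ff, fm, 0.95),
#'           n_reps_per_sex = 2000, seed = 1)
run_misid <- function(fit_f, fit_m, rule, n_reps_per_sex = 10000, seed = NULL,
                      adaptive = FALSE) {
  check_lognormal_pair(fit_f, fit_m)
  if (n_reps_per_sex < 100) {
    warn("fewer than 100 replicates per sex: rates will be unstable")
  }
  if (adaptive && inherits(rule, "empirical_rule")) {
    abort("adaptive thresholds apply only to probabilistic/continuous rules",
          class = "hatchsex_config_error")
  }
  ok_rule <- inherits(rule, "threshold_set") || inherits(rule, "continuous_rule")
  if (!ok_rule) abort("invalid rule", class = "hatchsex_config_error")

  res <- with_seed_maybe(seed, {
    assigned <- lapply(list(F_true = fit_f, M_true = fit_m), function(gen_fit) {
      par <- sample_ci_params(gen_fit, n_reps_per_sex)
      x <- rlnorm(n_reps_per_sex, par$meanlog, par$sdlog)
      if (!adaptive) {
        if (inherits(rule, "continuous_rule")) {
          p <- relative_prob_male(x, rule$fit_f, rule$fit_m, bin = rule$bin)
          ifelse(runif(n_reps_per_sex) < p, "M", "F")
        } else {
          assign_by_bounds(x, rule)
        }
      } else {
        pf <- sample_ci_params(fit_f, n_reps_per_sex)
        pm <- sample_ci_params(fit_m, n_reps_per_sex)
        p <- pointwise_prob_male(x, pf$meanlog, pf$sdlog, pm$meanlog, pm$sdlog)
        if (inherits(rule, "continuous_rule")) {
          ifelse(runif(n_reps_per_sex) < p, "M", "F")
        } else {
          cert <- rule$certainty
          dplyr::case_when(1 - p >= cert ~ "F", p >= cert ~ "M", TRUE ~ "U")
        }
      }
    })
    assigned
  })

  counts <- purrr::imap_dfr(res, function(a, true_lab) {
    tibble::tibble(true_sex = sub("_true", "", true_lab),
                   assigned_F = sum(a == "F"), assigned_M = sum(a == "M"),
                   assigned_U = sum(a == "U"))
  })
  cf <- counts[counts$true_sex == "F", ]
  cm <- counts[counts$true_sex == "M", ]
  pct <- function(err, tot) if (tot == 0) 0 else 100 * err / tot
  pct_f <- pct(cf$assigned_M, cf$assigned_F + cf$assigned_M)
  pct_m <- pct(cm$assigned_F, cm$assigned_F + cm$assigned_M)
  pct_u <- 100 * (cf$assigned_U + cm$assigned_U) / (2 * n_reps_per_sex)
  mc_se <- function(p, n) if (n == 0) NA_real_ else
    100 * sqrt((p / 100) * (1 - p / 100) / n)
  prop <- proportion_test(cf$assigned_F + cm$assigned_F,
                          cf$assigned_M + cm$assigned_M)

  structure(
    list(method = rule$method,
         certainty = if (is.numeric(rule$certainty)) rule$certainty else
           rule$method,
         rule = rule, adaptive = adaptive,
         n_reps_per_sex = n_reps_per_sex, counts = counts,
         pct_misidentified_f = pct_f, pct_misidentified_m = pct_m,
         pct_unknown = pct_u,
         mc_se_f = mc_se(pct_f, cf$assigned_F + cf$assigned_M),
         mc_se_m = mc_se(pct_m, cm$assigned_F + cm$assigned_M),
         prop_statistic = prop$statistic, prop_p = prop$p_value,
         seed = seed),
    class = "misid_report"
  )
}

# Pointwise (unbinned) relative probability of male; vectorised over
# observations and parameter draws alike.
pointwise_prob_male <- function(x, mf, sf, mm, sm) {
  ld <- dlnorm(x, mm, sm, log = TRUE) - dlnorm(x, mf, sf, log = TRUE)
  stats::plogis(ld)
}

#' @export
print.misid_report <- function(x, ...) {
  cat(sprintf("<misid_report: %s%s, %d reps/sex%s>\n", x$method,
              if (is.numeric(x$certainty))
                sprintf(" @ %.4g%%", 100 * x$certainty) else "",
              x$n_reps_per_sex, if (x$adaptive) ", adaptive" else ""))
  print(x$counts)
  cat(sprintf("  %% misidentified: F %.2f (SE %.3f), M %.2f (SE %.3f); %% unknown %.2f\n",
              x$pct_misidentified_f, x$mc_se_f, x$pct_misidentified_m,
              x$mc_se_m, x$pct_unknown))
  cat(sprintf("  F:M proportion test: X2 = %.3f, p = %.3g\n",
              x$prop_statistic, x$prop_p))
  invisible(x)
}

#' Tidy per-true-sex Monte Carlo tallies
#' @param x A `misid_report`.
#' @param ... Unused.
#' @return Tibble: one row per true sex with assignment counts and the
#'   misidentification percentage.
#' @exportS3Method generics::tidy
tidy.misid_report <- function(x, ...) {
  dplyr::mutate(x$counts,
                pct_misidentified = c(x$pct_misidentified_f,
                                      x$pct_misidentified_m))
}

#' One-row Monte Carlo summary
#' @inheritParams tidy.misid_report
#' @return One-row tibble with rates, Monte Carlo SEs and the proportion
#'   test.
#' @exportS3Method generics::glance
glance.misid_report <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    certainty = if (is.numeric(x$certainty)) x$certainty else NA_real_,
    adaptive = x$adaptive,
    n_reps_per_sex = x$n_reps_per_sex,
    pct_misidentified_f = x$pct_misidentified_f,
    pct_misidentified_m = x$pct_misidentified_m,
    pct_unknown = x$pct_unknown,
    mc_se_f = x$mc_se_f, mc_se_m = x$mc_se_m,
    prop_statistic = x$prop_statistic, prop_p = x$prop_p
  )
}

#' Closed-form misidentification rates at the point-estimate parameters
#'
#' Analytic counterpart of [run_misid()] for fixed-bound rules with no
#' parameter uncertainty: misidentification and unknown rates are exact
#' lognormal tail probabilities. Serves as the limiting oracle the Monte
#' Carlo converges to when the confidence intervals have zero width.
#'
#' @inheritParams run_misid
#' @return One-row tibble: `pct_misidentified_f`, `pct_misidentified_m`,
#'   `pct_unknown`.
#' @export
misid_closed_form <- function(fit_f, fit_m, rule) {
  check_lognormal_pair(fit_f, fit_m)
  stopifnot(inherits(rule, "threshold_set"))
  fu <- rule$female_upper
  ml <- rule$male_lower
  if (isTRUE(rule$overlap) && identical(rule$boundary, "exclusive")) {
    fu <- rule$male_min_obs
    ml <- rule$female_max_obs
  }
  ef <- fit_f$estimate
  em <- fit_m$estimate
  p_f_F <- plnorm(fu, ef[["meanlog"]], ef[["sdlog"]])        # true F assigned F
  p_f_M <- 1 - plnorm(ml, ef[["meanlog"]], ef[["sdlog"]])    # true F assigned M
  p_m_F <- plnorm(fu, em[["meanlog"]], em[["sdlog"]])
  p_m_M <- 1 - plnorm(ml, em[["meanlog"]], em[["sdlog"]])
  safe_pct <- function(err, tot) if (tot == 0) 0 else 100 * err / tot
  tibble::tibble(
    pct_misidentified_f = safe_pct(p_f_M, p_f_F + p_f_M),
    pct_misidentified_m = safe_pct(p_m_F, p_m_F + p_m_M),
    pct_unknown = 100 * (1 - (p_f_F + p_f_M + p_m_F + p_m_M) / 2)
  )
}

#' Test assigned F:M counts against an expected 50:50 split
#'
#' One-sample proportion test (chi-square form with Yates continuity
#' correction, 1 df) of the assigned-female fraction against 0.5, as used
#' to flag biased sex-assignment rules.
#'
#' @param n_assigned_f,n_assigned_m Non-negative counts.
#' @return One-row tibble: `statistic`, `p_value`, `prop_f`.
#' @export
#' @examples
#' proportion_test(8920, 9185)
proportion_test <- function(n_assigned_f, n_assigned_m) {
  if (n_assigned_f < 0 || n_assigned_m < 0 ||
      n_assigned_f + n_assigned_m == 0) {
    abort("counts must be non-negative with a positive total",
          class = "hatchsex_insufficient_data")
  }
  pt <- suppressWarnings(
    prop.test(n_assigned_f, n_assigned_f + n_assigned_m, p = 0.5,
              correct = TRUE))
  tibble::tibble(statistic = unname(pt$statistic), p_value = pt$p.value,
                 prop_f = unname(pt$estimate))
}
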