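#' Relative probability that a concentration came from the male distribution
#'
#' @description
#' The probabilistic sexing rule compares the fitted female and male
#' lognormal densities in a narrow concentration bin around the measured
#' value: the relative probability of male is
#' \deqn{p_M(x) = \frac{\int_{bin} f_M}{\int_{bin} f_M + \int_{bin} f_F}}
#' with the bin `[x - 0.05, x + 0.049]` pg/mL (clipped at zero), the
#' 0.1 pg/mL binning convention of the original analysis. The slightly
#' asymmetric upper edge is kept as published; set `bin = c(0.05, 0.05)`
#' for a symmetric bin (the difference is far below the reporting grid).
#' With equal (1:1) priors this is the posterior probability of male.
#'
#' @param x Concentration(s), pg/mL; must be > 0. Vectorised.
#' @param fit_f,fit_m [hormone_fit] objects (lognormal) for females and
#'   males.
#' @param bin Length-2 numeric: distances below and above `x` bounding the
#'   integration bin.
#' @return Numeric vector in `[0, 1]`, same length as `x`.
#' @export
#' @examples
#' relative_prob_male(37.7, reference_fit("F", "naive"), reference_fit("M", "naive"))
relative_prob_male <- function(x, fit_f, fit_m, bin = c(0.05, 0.049)) {
  check_lognormal_pair(fit_f, fit_m)
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("concentrations must be finite and > 0", class = "hatchsex_domain_error")
  }
  lo <- pmax(x - bin[1], 0)
  hi <- x + bin[2]
  ef <- fit_f$estimate
  em <- fit_m$estimate
  mass_m <- plnorm(hi, em[["meanlog"]], em[["sdlog"]]) -
    plnorm(lo, em[["meanlog"]], em[["sdlog"]])
  mass_f <- plnorm(hi, ef[["meanlog"]], ef[["sdlog"]]) -
    plnorm(lo, ef[["meanlog"]], ef[["sdlog"]])
  tot <- mass_m + mass_f
  # far in either tail both masses underflow; fall back to the log-density
  # ratio at the point, which is exact in the limit of a vanishing bin
  out <- ifelse(tot > 0, mass_m / tot, NA_real_)
  if (anyNA(out)) {
    ld <- dlnorm(x, em[["meanlog"]], em[["sdlog"]], log = TRUE) -
      dlnorm(x, ef[["meanlog"]], ef[["sdlog"]], log = TRUE)
    out[is.na(out)] <- stats::plogis(ld[is.na(out)])
  }
  out
}

check_lognormal_pair <- function(fit_f, fit_m) {
  stopifnot(inherits(fit_f, "hormone_fit"), inherits(fit_m, "hormone_fit"))
  if (fit_f$family != "lognormal" || fit_m$family != "lognormal") {
    abort("probabilistic assignment requires lognormal fits",
          class = "hatchsex_config_error")
  }
  if (any(!is.finite(c(fit_f$estimate, fit_m$estimate)))) {
    abort("fitted parameters must be finite", class = "hatchsex_domain_error")
  }
  invisible(TRUE)
}

#' Solve certainty thresholds for the probabilistic sexing rule
#'
#' @description
#' Finds, on a 0.1 pg/mL grid, the female upper bound (largest
#' concentration at which the relative probability of female is at least
#' the certainty level) and the male lower bound (smallest concentration
#' at which the relative probability of male is at least the certainty
#' level). At certainty 0.5 the two bounds coincide at the grid value
#' nearest the density crossing, giving a single decision threshold with
#' no unknown band.
#'
#' Because the male distribution is wider on the log scale, the densities
#' cross a second time at a biologically irrelevant, very low
#' concentration (about 0.23 pg/mL for the published naive parameters)
#' where the male density re-dominates; only the crossing between the two
#' distribution modes is used, and the default search range `[1, 10000]`
#' pg/mL (bracketing the assay's working range) excludes the spurious
#' crossing.
#'
#' @inheritParams relative_prob_male
#' @param certainty Certainty level in `[0.5, 1)`, e.g. 0.95.
#' @param grid_step Reporting grid, pg/mL.
#' @param search_range Length-2 numeric, pg/mL, bracketing the thresholds.
#' @return A `threshold_set`: list with `method = "probabilistic"`,
#'   `certainty`, `female_upper`, `male_lower`, `grid_step`.
#' @seealso [threshold_table()] for several certainty levels at once,
#'   [assign_sex()] to apply the rule.
#' @export
#' @examples
#' solve_thresholds(reference_fit("F", "naive"), reference_fit("M", "naive"), 0.95)
solve_thresholds <- function(fit_f, fit_m, certainty, grid_step = 0.1,
                             search_range = c(1, 10000), bin = c(0.05, 0.049)) {
  check_lognormal_pair(fit_f, fit_m)
  if (length(certainty) != 1 || certainty < 0.5 || certainty >= 1) {
    abort("certainty must be a single value in [0.5, 1)",
          class = "hatchsex_config_error")
  }
  ef <- fit_f$estimate
  em <- fit_m$estimate
  mode_f <- exp(ef[["meanlog"]] - ef[["sdlog"]]^2)
  mode_m <- exp(em[["meanlog"]] - em[["sdlog"]]^2)
  if (mode_f >= mode_m) {
    abort("female mode must lie below the male mode",
          class = "hatchsex_orientation_error")
  }
  grid <- seq(search_range[1], search_range[2], by = grid_step)
  p_m <- relative_prob_male(grid, fit_f, fit_m, bin = bin)
  p_f <- 1 - p_m

  # upward sign changes of p_m - 0.5 (the spurious low-concentration
  # crossing, where male density re-dominates, is a downward one); keep
  # the crossing adjacent to the inter-mode interval
  k <- length(grid)
  up <- which(p_m[-k] < 0.5 & p_m[-1] >= 0.5)
  up <- up[grid[up] >= mode_f - grid_step & grid[up] <= mode_m + grid_step]
  if (length(up) == 0) {
    abort("no density crossing between the modes inside the search range",
          class = "hatchsex_search_range_error")
  }
  cross_idx <- max(up)
  cross <- grid[cross_idx]

  if (certainty == 0.5) {
    # single threshold: grid value nearest the exact crossing
    cand <- c(cross_idx, cross_idx + 1)
    t50 <- grid[cand[which.min(abs(p_m[cand] - 0.5))]]
    return(new_threshold_set("probabilistic", certainty,
                             female_upper = t50, male_lower = t50,
                             grid_step = grid_step))
  }

  f_ok <- which(grid <= cross & p_f >= certainty)
  m_ok <- which(grid >= cross & p_m >= certainty)
  if (length(f_ok) == 0 || length(m_ok) == 0) {
    abort("certainty level not attained inside the search range",
          class = "hatchsex_search_range_error")
  }
  new_threshold_set("probabilistic", certainty,
                    female_upper = grid[max(f_ok)],
                    male_lower = grid[min(m_ok)],
                    grid_step = grid_step)
}

new_threshold_set <- function(method, certainty, female_upper, male_lower,
                              grid_step = 0.1, boundary = "inclusive") {
  structure(
    list(method = method, certainty = certainty,
         female_upper = unname(female_upper), male_lower = unname(male_lower),
         grid_step = grid_step, boundary = boundary),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  lab <- if (identical(x$certainty, "continuous")) "continuous" else
    if (is.numeric(x$certainty)) sprintf("%.4g%% certainty", 100 * x$certainty) else
      x$certainty
  if (!is.null(x$female_upper) && x$female_upper == x$male_lower) {
    cat(sprintf("<threshold_set: %s, %s> F < %.1f < M\n", x$method, lab,
                x$female_upper))
  } else {
    cat(sprintf("<threshold_set: %s, %s> F <= %.1f < U < %.1f <= M\n",
                x$method, lab, x$female_upper, x$male_lower))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.threshold_set <- function(x, ...) {
  tibble::tibble(method = x$method,
                 certainty = if (is.numeric(x$certainty)) x$certainty else NA_real_,
                 female_upper = x$female_upper, male_lower = x$male_lower,
                 grid_step = x$grid_step)
}

#' Threshold table across certainty levels
#'
#' Solves the probabilistic thresholds at several certainty levels and
#' returns one tidy row per level — the shape of a published threshold
#' table.
#'
#' @inheritParams solve_thresholds
#' @param certainty Numeric vector of certainty levels.
#' @return Tibble with columns `certainty`, `female_upper`, `male_lower`.
#' @export
#' @examples
#' threshold_table(reference_fit("F", "naive"), reference_fit("M", "naive"))
threshold_table <- function(fit_f, fit_m,
                            certainty = c(0.5, 0.8, 0.95, 0.9999),
                            grid_step = 0.1, search_range = c(1, 10000)) {
  purrr::map_dfr(certainty, function(cl) {
    ts <- solve_thresholds(fit_f, fit_m, cl, grid_step, search_range)
    tibble::tibble(certainty = cl, female_upper = ts$female_upper,
                   male_lower = ts$male_lower)
  })
}

#' Empirical-range sexing rule from observed known-sex concentrations
#'
#' @description
#' Builds the range-based decision rule from observed female and male
#' concentrations. When the observed ranges do not overlap, a sample is
#' female if at or below the highest observed female value, male if at or
#' above the lowest observed male value, and unknown in between. When
#' they overlap, the default (`overlap = "strict"`) assigns female
#' strictly below the lowest male observation and male strictly above the
#' highest female observation, leaving the whole overlap region unknown;
#' `overlap = "exclude_overlap"` instead uses the first female and male
#' observations outside the overlap as inclusive bounds.
#'
#' @param female,male Numeric vectors of observed concentrations (pg/mL)
#'   for confirmed females and males (extrema alone suffice for the
#'   non-overlapping and `"strict"` cases).
#' @param overlap Rule applied when the observed ranges overlap.
#' @param grid_step Reporting precision for the displayed bounds in the
#'   `"strict"` overlap case.
#' @return An `empirical_rule` object usable with [assign_sex()].
#' @export
#' @examples
#' empirical_rule(female = c(7.8, 20.8), male = c(125.4, 651.4))
empirical_rule <- function(female, male,
                           overlap = c("strict", "exclude_overlap"),
                           grid_step = 0.1) {
  overlap <- match.arg(overlap)
  if (any(c(female, male) <= 0)) {
    abort("observed concentrations must be > 0", class = "hatchsex_domain_error")
  }
  f_max <- max(female)
  m_min <- min(male)
  if (f_max < m_min) {
    rule <- new_threshold_set("empirical", "range", female_upper = f_max,
                              male_lower = m_min, grid_step = grid_step)
    rule$overlap <- FALSE
  } else if (overlap == "strict") {
    # F strictly below the male minimum, M strictly above the female
    # maximum; displayed bounds snapped one grid step inside
    rule <- new_threshold_set("empirical", "range",
                              female_upper = m_min - grid_step,
                              male_lower = f_max + grid_step,
                              grid_step = grid_step, boundary = "exclusive")
    rule$overlap <- TRUE
    rule$male_min_obs <- m_min
    rule$female_max_obs <- f_max
  } else {
    f_out <- female[female < m_min]
    m_out <- male[male > f_max]
    if (length(f_out) == 0 || length(m_out) == 0) {
      abort("no observations outside the overlap region",
            class = "hatchsex_domain_error")
    }
    rule <- new_threshold_set("empirical", "range",
                              female_upper = max(f_out),
                              male_lower = min(m_out), grid_step = grid_step)
    rule$overlap <- TRUE
  }
  class(rule) <- c("empirical_rule", class(rule))
  rule
}

#' Continuous (weighted coin) sexing rule
#'
#' Every sample is assigned F or M — never unknown — by a Bernoulli draw
#' with success probability equal to the relative probability of male at
#' the sample concentration.
#'
#' @inheritParams relative_prob_male
#' @return A `continuous_rule` object for [assign_sex()].
#' @export
continuous_rule <- function(fit_f, fit_m, bin = c(0.05, 0.049)) {
  check_lognormal_pair(fit_f, fit_m)
  structure(list(method = "continuous", fit_f = fit_f, fit_m = fit_m, bin = bin),
            class = "continuous_rule")
}

# Vectorised core assignment for fixed-bound rules.
assign_by_bounds <- function(x, rule) {
  if (isTRUE(rule$overlap) && identical(rule$boundary, "exclusive")) {
    dplyr::case_when(x < rule$male_min_obs ~ "F",
                     x > rule$female_max_obs ~ "M",
                     TRUE ~ "U")
  } else {
    dplyr::case_when(x <= rule$female_upper ~ "F",
                     x >= rule$male_lower ~ "M",
                     TRUE ~ "U")
  }
}

#' Assign sex to sampled concentrations
#'
#' @description
#' Applies a sexing rule to a cohort. `data` is a data frame with a
#' `testosterone_pg_ml` column (or a bare numeric vector); the result is
#' the input tibble with columns `assigned` (`"F"`, `"M"`, `"U"`) and,
#' when the rule carries fitted distributions, `prob_male` and
#' `prob_female` appended.
#'
#' Rules: a `threshold_set` from [solve_thresholds()] (deterministic,
#' with an unknown band unless certainty is 0.5), an [empirical_rule()]
#' (deterministic), or a [continuous_rule()] (a weighted coin; supply
#' `seed` for reproducibility, never assigns unknown).
#'
#' @param data Data frame with `testosterone_pg_ml`, or numeric vector.
#' @param rule A `threshold_set`, `empirical_rule` or `continuous_rule`.
#' @param fit_f,fit_m Optional lognormal fits used to append probabilities
#'   when the rule itself does not carry them.
#' @param seed Optional seed for the continuous rule's coin.
#' @return A tibble; input columns plus `assigned`, and `prob_male` /
#'   `prob_female` when available.
#' @export
#' @examples
#' ts <- solve_thresholds(reference_fit("F", "naive"),
#'                        reference_fit("M", "naive"), 0.95)
#' assign_sex(c(10, 37, 100), ts)
assign_sex <- function(data, rule, fit_f = NULL, fit_m = NULL, seed = NULL) {
  df <- if (is.data.frame(data)) tibble::as_tibble(data) else
    tibble::tibble(testosterone_pg_ml = as.numeric(data))
  x <- df$testosterone_pg_ml
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("concentrations must be finite and > 0", class = "hatchsex_domain_error")
  }
  if (inherits(rule, "continuous_rule")) {
    p <- relative_prob_male(x, rule$fit_f, rule$fit_m, bin = rule$bin)
    df$assigned <- with_seed_maybe(seed,
      ifelse(runif(length(x)) < p, "M", "F"))
    df$prob_male <- p
    df$prob_female <- 1 - p
  } else if (inherits(rule, "threshold_set")) {
    df$assigned <- assign_by_bounds(x, rule)
    if (!is.null(fit_f) && !is.null(fit_m)) {
      p <- relative_prob_male(x, fit_f, fit_m)
      df$prob_male <- p
      df$prob_female <- 1 - p
    }
  } else {
    abort("unknown rule type", class = "hatchsex_config_error")
  }
  df
}
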