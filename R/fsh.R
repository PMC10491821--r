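# Paired-sample utilities -----------------------------------------------

# Accepts either wide pairs (individual_id, sex, t_naive, t_challenged) or
# long sample records (individual_id, sex, status, testosterone_pg_ml);
# returns complete wide pairs, dropping incomplete individuals with a
# warning.
normalise_pairs <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (all(c("t_naive", "t_challenged") %in% names(pairs))) {
    wide <- pairs
  } else if (all(c("status", "testosterone_pg_ml") %in% names(pairs))) {
    wide <- tidyr::pivot_wider(
      dplyr::select(pairs, "individual_id", "sex", "status",
                    "testosterone_pg_ml"),
      names_from = "status", values_from = "testosterone_pg_ml",
      names_prefix = "t_")
    if (!all(c("t_naive", "t_challenged") %in% names(wide))) {
      abort("need both naive and challenged samples",
            class = "hatchsex_pairing_error")
    }
  } else {
    abort("pairs must be wide (t_naive, t_challenged) or long (status, testosterone_pg_ml)",
          class = "hatchsex_schema_error")
  }
  incomplete <- !stats::complete.cases(wide[, c("t_naive", "t_challenged")])
  if (any(incomplete)) {
    warn(sprintf("dropping %d individual(s) lacking one of the paired samples",
                 sum(incomplete)))
    wide <- wide[!incomplete, ]
  }
  if (anyDuplicated(wide$individual_id)) {
    abort("each individual must contribute exactly one pair",
          class = "hatchsex_pairing_error")
  }
  if (any(wide$t_naive <= 0) || any(wide$t_challenged <= 0)) {
    abort("concentrations must be > 0", class = "hatchsex_domain_error")
  }
  wide
}

#' Repeated-measures ANOVA for the FSH-challenge effect on paired samples
#'
#' @description
#' Tests whether an FSH challenge elevates testosterone differently in
#' males and females. Fits the classical 2x2 mixed ANOVA on paired
#' (naive, challenged) concentrations — sex as the between-subjects
#' factor, challenge status (and its interaction with sex) within
#' subjects — via an individual-level error stratum. The sex-by-status
#' interaction is the test of a differential FSH response; its F has
#' degrees of freedom (1, n - 2) for n paired individuals.
#' Concentrations are log-transformed by default to meet the normality
#' assumption. With one between factor and complete pairs the design is
#' balanced within subjects, so these F tests coincide with their Type
#' III counterparts.
#'
#' Assumption checks reported alongside: Levene's test (median-centred)
#' for homogeneity of variance across the four sex-by-status cells, and
#' Shapiro-Wilk normality of the model residuals.
#'
#' @param pairs Paired samples, wide (`individual_id`, `sex`, `t_naive`,
#'   `t_challenged`) or long (`individual_id`, `sex`, `status`,
#'   `testosterone_pg_ml`). Incomplete pairs are dropped with a warning.
#' @param log_transform Analyse log concentrations (default `TRUE`).
#' @return An `fsh_anova` object; `tidy()` gives the term table,
#'   `glance()` the one-row summary.
#' @export
#' @examples
#' pairs <- simulate_paired_fsh(generator_config(n_female = 8, n_male = 8, seed = 1))
#' fsh_anova(pairs)
fsh_anova <- function(pairs, log_transform = TRUE) {
  wide <- normalise_pairs(pairs)
  if (length(unique(wide$sex)) < 2) {
    abort("need both sexes to test an interaction", class = "hatchsex_design_error")
  }
  if (any(table(wide$sex) < 2)) {
    abort("need at least 2 individuals per sex", class = "hatchsex_design_error")
  }
  long <- tidyr::pivot_longer(wide, c("t_naive", "t_challenged"),
                              names_to = "status", values_to = "conc",
                              names_prefix = "t_")
  long$status <- factor(long$status, levels = c("naive", "challenged"))
  long$sex <- factor(long$sex)
  long$individual_id <- factor(long$individual_id)
  long$y <- if (log_transform) log(long$conc) else long$conc

  fit <- aov(y ~ sex * status + Error(individual_id), data = long)
  within_tab <- summary(fit)[["Error: Within"]][[1]]
  row <- function(tab, name) {
    tab[which(trimws(rownames(tab)) == name), ]
  }
  resid_row <- row(within_tab, "Residuals")
  resid_ms <- resid_row[["Mean Sq"]]
  scale_tol <- 1e-10 * max(1, mean(long$y^2))
  f_of <- function(name) {
    r <- row(within_tab, name)
    df <- c(r[["Df"]], resid_row[["Df"]])
    if (r[["Mean Sq"]] <= scale_tol) {
      list(f = 0, p = 1, df = df)                    # no effect at all
    } else if (resid_ms <= scale_tol) {
      list(f = Inf, p = 0, df = df)                  # zero residual variance
    } else {
      list(f = r[["F value"]], p = r[["Pr(>F)"]], df = df)
    }
  }
  inter <- f_of("sex:status")
  main <- f_of("status")

  lev <- car::leveneTest(y ~ sex * status, data = long)
  fixed <- lm(y ~ individual_id + sex * status, data = long)
  sw <- tryCatch(shapiro.test(resid(fixed))$p.value, error = function(e) NA_real_)

  structure(
    list(f_interaction = inter$f, p_interaction = inter$p, df = inter$df,
         f_status = main$f, p_status = main$p,
         levene_p = lev[["Pr(>F)"]][1], shapiro_p = sw,
         transformed = log_transform,
         n = nrow(wide), n_by_sex = table(wide$sex)),
    class = "fsh_anova"
  )
}

#' @export
print.fsh_anova <- function(x, ...) {
  cat(sprintf("<fsh_anova: %d pairs (%s)%s>\n", x$n,
              paste(names(x$n_by_sex), as.integer(x$n_by_sex),
                    sep = "=", collapse = ", "),
              if (x$transformed) ", log scale" else ""))
  cat(sprintf("  sex x status interaction: F(%d, %d) = %.3g, p = %.3g\n",
              x$df[1], x$df[2], x$f_interaction, x$p_interaction))
  cat(sprintf("  challenge main effect:    F = %.3g, p = %.3g\n",
              x$f_status, x$p_status))
  cat(sprintf("  Levene p = %.3g; Shapiro-Wilk p = %.3g\n",
              x$levene_p, x$shapiro_p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fsh_anova <- function(x, ...) {
  tibble::tibble(
    term = c("status", "sex:status"),
    statistic = c(x$f_status, x$f_interaction),
    p.value = c(x$p_status, x$p_interaction),
    df = x$df[1], df.residual = x$df[2]
  )
}

#' @exportS3Method generics::glance
glance.fsh_anova <- function(x, ...) {
  tibble::tibble(
    f_interaction = x$f_interaction, p_interaction = x$p_interaction,
    df_num = x$df[1], df_den = x$df[2],
    f_status = x$f_status, p_status = x$p_status,
    levene_p = x$levene_p, shapiro_p = x$shapiro_p,
    transformed = x$transformed, n_pairs = x$n
  )
}

#' Permutation test of the sex difference in FSH-induced change
#'
#' @description
#' Distribution-free companion to [fsh_anova()]: the statistic is the
#' male-minus-female difference in mean per-individual change from naive
#' to challenged, on the absolute (pg/mL) or percent scale. Sex labels
#' are permuted across individuals; the two-sided p-value is the
#' proportion of permutations (observed labelling included, so p is
#' never 0) with an absolute statistic at least as large as observed.
#' When every relabelling can be enumerated (`n_perm` at least the number
#' of distinct label splits), the test is exact by full enumeration.
#'
#' @inheritParams fsh_anova
#' @param scale `"absolute"` (challenged - naive, pg/mL) or `"percent"`
#'   (100 x change / naive).
#' @param n_perm Number of random permutations (>= 999), or at least
#'   `choose(n, n_F)` to trigger exhaustive enumeration.
#' @param seed Optional seed for the random permutations.
#' @return One-row tibble: `observed_diff`, `p_value`, `n_perm`,
#'   `exhaustive`.
#' @export
permutation_change_test <- function(pairs, scale = c("absolute", "percent"),
                                    n_perm = 9999, seed = NULL) {
  scale <- match.arg(scale)
  wide <- normalise_pairs(pairs)
  if (length(unique(wide$sex)) < 2 || any(table(wide$sex) < 2)) {
    abort("need at least 2 individuals per sex", class = "hatchsex_design_error")
  }
  if (n_perm < 999) abort("n_perm must be >= 999", class = "hatchsex_config_error")
  change <- switch(scale,
    absolute = wide$t_challenged - wide$t_naive,
    percent = 100 * (wide$t_challenged - wide$t_naive) / wide$t_naive)
  is_m <- wide$sex == "M"
  stat <- function(male_idx) {
    mean(change[male_idx]) - mean(change[-male_idx])
  }
  obs <- stat(which(is_m))
  n <- length(change)
  n_m <- sum(is_m)
  n_splits <- choose(n, n_m)

  if (n_splits <= n_perm) {
    splits <- utils::combn(n, n_m)
    perm <- apply(splits, 2, stat)
    p <- mean(abs(perm) >= abs(obs) - 1e-12)
    return(tibble::tibble(observed_diff = obs, p_value = p,
                          n_perm = ncol(splits), exhaustive = TRUE))
  }
  perm <- with_seed_maybe(seed, vapply(seq_len(n_perm), function(i) {
    stat(sample.int(n, n_m))
  }, 0))
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  tibble::tibble(observed_diff = obs, p_value = p, n_perm = n_perm,
                 exhaustive = FALSE)
}
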