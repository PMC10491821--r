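#' Configuration for the synthetic hormone-panel generators
#'
#' @description
#' Collects the generative assumptions the analysis makes about hatchling
#' testosterone: sex-specific lognormal concentration distributions, and
#' an FSH challenge acting as an additive shift on the log scale
#' (multiplicative on pg/mL) plus log-scale Gaussian noise, with no
#' sex-by-challenge interaction by default.
#'
#' Defaults reproduce the published study conditions: panel sizes 6
#' females / 18 males; naive lognormal parameters from
#' [tortoise_reference_fits]; per-sex FSH shifts equal to the published
#' challenged-minus-naive `meanlog` differences (0.99 for females, 0.85
#' for males — both sexes increase, with no differential response); and
#' log-scale residual SD 0.6, consistent with the widening from the naive
#' to the challenged `sdlog` under independent noise.
#'
#' @param n_female,n_male Non-negative counts.
#' @param params_female,params_male Length-2 numeric `(meanlog, sdlog)`
#'   of the naive lognormal concentration distribution, log-pg/mL.
#' @param challenged_params_female,challenged_params_male `(meanlog,
#'   sdlog)` used when generating stand-alone challenged panels.
#' @param fsh_shift Named numeric `c(f = , m = )`: additive log-scale
#'   shift from naive to challenged per sex.
#' @param fsh_noise_sd Log-scale residual SD of the paired shift (>= 0).
#' @param seed Optional integer seed; identical seed and configuration
#'   give identical output.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_female = 6, n_male = 18,
                             params_female = c(2.46, 0.29),
                             params_male = c(5.69, 0.53),
                             challenged_params_female = c(3.45, 0.68),
                             challenged_params_male = c(6.54, 0.85),
                             fsh_shift = c(f = 0.99, m = 0.85),
                             fsh_noise_sd = 0.6,
                             seed = NULL) {
  cfg <- list(n_female = n_female, n_male = n_male,
              params_female = params_female, params_male = params_male,
              challenged_params_female = challenged_params_female,
              challenged_params_male = challenged_params_male,
              fsh_shift = fsh_shift, fsh_noise_sd = fsh_noise_sd, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_config <- function(cfg) {
  if (cfg$n_female < 0 || cfg$n_male < 0) {
    abort("counts must be >= 0", class = "hatchsex_config_error")
  }
  sds <- c(cfg$params_female[2], cfg$params_male[2],
           cfg$challenged_params_female[2], cfg$challenged_params_male[2],
           cfg$fsh_noise_sd)
  if (any(sds < 0)) {
    abort("sdlog values must be >= 0", class = "hatchsex_config_error")
  }
  invisible(cfg)
}

sample_record <- function(individual_id, sex, status, testosterone,
                          cohort = "sim", latent_sex = NULL) {
  out <- tibble::tibble(
    individual_id = individual_id, cohort = cohort, sex = sex,
    status = status, testosterone_pg_ml = testosterone)
  if (!is.null(latent_sex)) out$latent_sex <- latent_sex
  out
}

#' Simulate a known-sex testosterone panel
#'
#' Draws naive or challenged concentrations from the configured
#' sex-specific lognormal distributions, one row per animal, in the
#' sample-record schema the rest of the pipeline consumes.
#'
#' @param config A [generator_config()].
#' @param status `"naive"` or `"challenged"`; selects which configured
#'   parameter pair generates the panel.
#' @return Tibble: `individual_id`, `cohort`, `sex`, `status`,
#'   `testosterone_pg_ml`.
#' @export
#' @examples
#' simulate_known_sex(generator_config(seed = 1))
simulate_known_sex <- function(config = generator_config(),
                               status = c("naive", "challenged")) {
  validate_config(config)
  status <- match.arg(status)
  pf <- if (status == "naive") config$params_female else
    config$challenged_params_female
  pm <- if (status == "naive") config$params_male else
    config$challenged_params_male
  with_seed_maybe(config$seed, {
    conc <- c(rlnorm(config$n_female, pf[1], pf[2]),
              rlnorm(config$n_male, pm[1], pm[2]))
    n <- config$n_female + config$n_male
    sample_record(
      individual_id = sprintf("sim_%03d", seq_len(n)),
      sex = rep(c("F", "M"), c(config$n_female, config$n_male)),
      status = status, testosterone = conc)
  })
}

#' Simulate paired naive and FSH-challenged samples
#'
#' Each individual receives a naive draw from its sex's naive lognormal
#' and a challenged value equal to the naive value shifted on the log
#' scale by the sex-specific FSH effect plus Gaussian noise:
#' `log T_chal = log T_naive + delta_sex + N(0, fsh_noise_sd)`. Equal
#' shifts for the two sexes (the default) generate data under the null of
#' no sex-by-challenge interaction.
#'
#' @inheritParams simulate_known_sex
#' @return Long tibble, two rows per individual (`status` `"naive"` and
#'   `"challenged"`), linked by `individual_id`.
#' @export
#' @examples
#' simulate_paired_fsh(generator_config(n_female = 5, n_male = 5, seed = 1))
simulate_paired_fsh <- function(config = generator_config()) {
  validate_config(config)
  with_seed_maybe(config$seed, {
    n <- config$n_female + config$n_male
    sex <- rep(c("F", "M"), c(config$n_female, config$n_male))
    id <- sprintf("sim_%03d", seq_len(n))
    mu <- ifelse(sex == "F", config$params_female[1], config$params_male[1])
    sig <- ifelse(sex == "F", config$params_female[2], config$params_male[2])
    log_naive <- rnorm(n, mu, sig)
    delta <- ifelse(sex == "F", config$fsh_shift[["f"]], config$fsh_shift[["m"]])
    log_chal <- log_naive + delta + rnorm(n, 0, config$fsh_noise_sd)
    dplyr::bind_rows(
      sample_record(id, sex, "naive", exp(log_naive)),
      sample_record(id, sex, "challenged", exp(log_chal)))
  })
}

#' Simulate an unknown-sex wild cohort
#'
#' Mixture draw from the configured female and male distributions; the
#' public `sex` label is `"U"` while the generating (latent) sex is kept
#' in a clearly named `latent_sex` column so validation code can score
#' assignments without leaking labels to the classifier path.
#'
#' @inheritParams simulate_known_sex
#' @param mix_prop_male Probability in `[0, 1]` that an individual is
#'   latent-male.
#' @param n Cohort size; defaults to `n_female + n_male` of the config.
#' @return Tibble in the sample-record schema with `sex = "U"` plus
#'   `latent_sex`.
#' @export
simulate_wild_cohort <- function(config = generator_config(),
                                 mix_prop_male = 0.5,
                                 n = config$n_female + config$n_male,
                                 status = c("naive", "challenged")) {
  validate_config(config)
  status <- match.arg(status)
  if (mix_prop_male < 0 || mix_prop_male > 1) {
    abort("mix_prop_male must be in [0, 1]", class = "hatchsex_config_error")
  }
  pf <- if (status == "naive") config$params_female else
    config$challenged_params_female
  pm <- if (status == "naive") config$params_male else
    config$challenged_params_male
  with_seed_maybe(config$seed, {
    latent <- ifelse(runif(n) < mix_prop_male, "M", "F")
    conc <- ifelse(latent == "M", rlnorm(n, pm[1], pm[2]),
                   rlnorm(n, pf[1], pf[2]))
    sample_record(sprintf("wild_%03d", seq_len(n)), sex = "U",
                  status = status, testosterone = conc, cohort = "wild",
                  latent_sex = latent)
  })
}

#' Simulate an ELISA dilution-series plate
#'
#' Generates a twofold dilution series with responses on a 4PL curve plus
#' Gaussian noise, in duplicate (or any replicate count) — the synthetic
#' counterpart of running a kit standard or pooled-sample series.
#'
#' @param params Named numeric `c(b, c, d, e)` of the generating 4PL
#'   curve (see [fit_4pl()]).
#' @param top_conc Highest concentration of the series, pg/mL.
#' @param dilution_steps Number of twofold dilutions (>= 3; at least 5
#'   are needed to fit all four parameters downstream).
#' @param noise_sd Gaussian response noise, %B/B0 units.
#' @param duplicates Replicate wells per concentration (>= 1).
#' @param series_id,plate_id Identifier columns of the output.
#' @param seed Optional seed.
#' @return Tibble: `plate_id`, `series_id`, `dilution_step`,
#'   `concentration`, `response_bb0`, `replicate`.
#' @export
#' @examples
#' simulate_plate(noise_sd = 2, seed = 1)
simulate_plate <- function(params = c(b = 1, c = 0, d = 100, e = 50),
                           top_conc = 500, dilution_steps = 8, noise_sd = 0,
                           duplicates = 2, series_id = "standard",
                           plate_id = "plate_1", seed = NULL) {
  if (dilution_steps < 3) {
    abort("need at least 3 dilution steps", class = "hatchsex_config_error")
  }
  if (duplicates < 1 || noise_sd < 0) {
    abort("duplicates must be >= 1 and noise_sd >= 0",
          class = "hatchsex_config_error")
  }
  step <- seq_len(dilution_steps)
  conc <- top_conc / 2^(step - 1)
  grid <- tidyr::expand_grid(dilution_step = step,
                             replicate = seq_len(duplicates))
  grid$concentration <- conc[grid$dilution_step]
  mu <- fourpl(grid$concentration, params[["b"]], params[["c"]],
               params[["d"]], params[["e"]])
  with_seed_maybe(seed, {
    tibble::tibble(
      plate_id = plate_id, series_id = series_id,
      dilution_step = grid$dilution_step,
      concentration = grid$concentration,
      response_bb0 = mu + rnorm(nrow(grid), 0, noise_sd),
      replicate = grid$replicate)
  })
}
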