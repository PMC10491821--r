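# Reference fits (published point estimates + CIs) used across tests.
naive_f <- reference_fit("F", "naive")
naive_m <- reference_fit("M", "naive")
chal_f <- reference_fit("F", "challenged")
chal_m <- reference_fit("M", "challenged")

# A lognormal fit object from bare parameters, with optional CI box.
make_lnorm_fit <- function(meanlog, sdlog, ci = NULL, data = NULL) {
  hatchsex:::new_hormone_fit(
    family = "lognormal",
    estimate = c(meanlog = meanlog, sdlog = sdlog),
    n = if (is.null(data)) NA_integer_ else length(data),
    ci = ci, data = data)
}

# Zero-uncertainty versions of the reference fits (point estimates only).
point_fit <- function(fit) make_lnorm_fit(fit$estimate[["meanlog"]],
                                          fit$estimate[["sdlog"]])

# A bare single-threshold rule at concentration t (50%-style, no unknown).
new_threshold_set_for_test <- function(t) {
  hatchsex:::new_threshold_set("probabilistic", 0.5,
                               female_upper = t, male_lower = t)
}

# Small deterministic paired-sample table: per-individual log changes are
# delta_f for females and delta_m for males plus optional noise.
make_pairs <- function(n_f, n_m, delta_f, delta_m, noise_sd = 0, seed = 1) {
  cfg <- generator_config(n_female = n_f, n_male = n_m,
                          fsh_shift = c(f = delta_f, m = delta_m),
                          fsh_noise_sd = noise_sd, seed = seed)
  simulate_paired_fsh(cfg)
}
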