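---
title: "Hormone-based sex identification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hormone-based sex identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hatchsex)
```

## The problem

Many turtles, including the Mojave desert tortoise (*Gopherus
agassizii*), have temperature-dependent sex determination and are
externally sexually monomorphic for years after hatching. Surgical
inspection of the gonads (coelioscopy) is accurate but invasive;
hatchling conservation work needs a method that works on a single field
encounter. Plasma testosterone quantified by competitive ELISA from a
0.1 mL blood sample is such a method: confirmed-sex hatchling panels
show strongly separated male and female concentration distributions,
and a decision rule built from those distributions can sex an unknown
hatchling with a quantifiable error rate.

`hatchsex` implements that full analysis: distribution fitting with
bootstrap uncertainty, threshold derivation, Monte Carlo
misidentification rates, the test of an FSH (follicle-stimulating
hormone) challenge effect, and ELISA curve validation — plus synthetic
generators for every input, so the machinery is testable without any
animal data.

## Sex-specific concentration model

Within a sex `s` and challenge status, testosterone concentration
(pg/mL) is modelled as lognormal,
$T \sim \mathrm{Lognormal}(\mu_s, \sigma_s)$. `fit_hormone_dist()`
computes the closed-form MLE ($\hat\mu$ = mean of log values,
$\hat\sigma$ = RMS deviation of logs with divisor $n$ — the true MLE;
the $n-1$ variant would visibly shift $\hat\sigma$ at panel sizes of
6–22). Gamma and Weibull alternatives are fitted through
`fitdistrplus`; on real hatchling panels the lognormal is the family
that fits all sex-by-status subsets.

Parameter uncertainty comes from a nonparametric bootstrap
(`bootstrap_ci()`, percentile intervals, conventionally 10,000
iterations). Refits that fail — a degenerate resample, a non-converging
gamma fit — are dropped and counted; more than 50% failures aborts.
Percentile rather than BCa intervals are used, matching the default of
the standard distribution-fitting tooling. Goodness of fit is the
one-sample Kolmogorov–Smirnov test with parameters treated as known
(`ks_gof()`); because the parameters were estimated from the same data
this p-value is conservative, which we document rather than correct —
it matches how such D/p pairs are conventionally reported alongside the
parameter table.

The published reference parameters ship in `tortoise_reference_fits`
(and `reference_fit()`), so thresholds and error rates can be computed
in the field without raw data:

```{r}
tortoise_reference_fits
```

## The probabilistic decision rule

For fits $f_F$, $f_M$ the relative probability of male at concentration
$x$ integrates both densities over a 0.1 pg/mL bin:

$$p_M(x) = \frac{\int_{x-0.05}^{x+0.049} f_M}
                {\int_{x-0.05}^{x+0.049} f_M + \int_{x-0.05}^{x+0.049} f_F},$$

i.e. the posterior probability of male under equal (1:1) priors. The
slightly asymmetric upper bin edge (+0.049, not +0.05) is kept exactly
as the procedure was originally specified; a symmetric bin is available
via the `bin` argument and moves no reported threshold by more than one
grid step. The bin is clipped at zero for the (practically unreachable)
case $x < 0.05$.

`solve_thresholds()` reports, on a 0.1 pg/mL grid over a default search
range of 1–10,000 pg/mL (the assay's working range):

* the female upper bound — the largest grid value with
  $1 - p_M(x) \ge$ the certainty level;
* the male lower bound — the smallest grid value with $p_M(x) \ge$ the
  certainty level;
* at certainty 0.5 both collapse to the single grid value nearest the
  density crossing (the value minimising $|p_M - 0.5|$); this snapping
  convention is the one that reproduces the published single thresholds
  for both the naive (37.7) and challenged (129.7) panels, whose exact
  crossings fall on opposite sides of their grid midpoints.

Because $\sigma_M > \sigma_F$, the two lognormal densities cross twice;
below the second, very low crossing (about 0.23 pg/mL for the naive
parameters) the male density re-dominates. The solver uses only the
upward crossing adjacent to the inter-mode interval, and the default
search range excludes the spurious region entirely.

```{r}
threshold_table(reference_fit("F", "naive"), reference_fit("M", "naive"))
```

Three assignment modes (`assign_sex()`): thresholds with an unknown
band; the continuous "weighted coin" (`continuous_rule()`), which
assigns every sample F or M with probability $p_M(x)$ and never answers
unknown; and the empirical range rule (`empirical_rule()`) built from
observed extrema. When the observed sex ranges overlap, the default
empirical rule assigns F strictly below the lowest male observation and
M strictly above the highest female observation (reported bounds
snapped one grid step inside, matching how the published overlap-case
bounds were printed); the alternative — first observations *outside*
the overlap as inclusive bounds — is available as
`overlap = "exclude_overlap"`. Both conventions appear in the source
material, which states the outside-overlap wording but prints
strict-overlap bounds; we default to the printed behaviour.

One published cell deserves a note: the challenged-panel 99.99% male
bound is printed as 423.2 pg/mL, but under the stated rule that value
is the 99.9% solution; the true 99.99% bound from the same parameters
is 605.3 pg/mL (the female bound printed beside it, 17.5, *is* the
true 99.99% solution, as are both naive 99.99% bounds). The solver is
faithful to the stated certainty, so it returns 605.3.

## Monte Carlo misidentification rates

`run_misid()` estimates the operating characteristics of any rule. Per
replicate, for each true sex: draw $(\mu, \sigma)$ independently and
uniformly within the 95% bootstrap CI box, draw one concentration from
that lognormal, and assign. Unknown assignments are excluded from the
misidentification denominators (per-true-sex: true females assigned M
over true females assigned F or M). A Yates-corrected chi-square
proportion test checks the pooled assigned F:M split against 50:50.

By default the decision thresholds are held fixed at the
point-estimate solution while generation uses CI-sampled parameters —
the reading most consistent with how the procedure is described. The
alternative, recomputing the rule per replicate from a fresh CI-sampled
parameter pair (`adaptive = TRUE`, using the pointwise density ratio),
is also provided: the two variants bracket the ambiguity in how
generation and assignment uncertainty can be linked, and some published
nonzero misidentification percentages fall between them. We report
both rather than forcing agreement; `misid_closed_form()` provides the
exact zero-uncertainty limit both converge to, which the test suite
verifies within Monte Carlo error.

## FSH challenge analysis

Whether FSH differentially elevates testosterone in males is tested on
paired (naive, challenged) samples by the classical 2×2 mixed ANOVA
(`fsh_anova()`): sex between subjects, challenge status within, the
sex-by-status interaction being the effect of interest, with F on
$(1, n-2)$ df. Concentrations are log-transformed by default; the
challenge then acts additively on the log scale, which is also how the
generator models it. With a single between factor and complete pairs
the design is balanced within subjects, so these F tests coincide with
their Type III counterparts (the sums-of-squares type only matters for
richer designs). Levene's test across the four cells and Shapiro–Wilk
on residuals are reported alongside. Individuals missing either sample
are dropped with a warning. Degenerate inputs are handled explicitly:
zero interaction mean square reports F = 0, p = 1; zero residual
variance with a real effect reports F = Inf, p = 0.

`permutation_change_test()` is the distribution-free companion: the
statistic is the M−F difference in mean per-individual change
(absolute pg/mL or percent), sex labels are permuted, and the p-value
includes the observed labelling so it is never zero. When
$\binom{n}{n_F}$ label splits fit within `n_perm` the test enumerates
them exactly.

## ELISA validation

Dose–response calibration uses the four-parameter logistic on the
log-concentration axis,
$y = c + (d - c) / (1 + e^{b(\ln x - \ln e)})$, fitted by
Levenberg–Marquardt least squares (`fit_4pl()`); $e$ is the inflection
concentration (ED50) and $b$ the slope there. Parallelism between the
kit standard and a pooled-sample dilution series (`parallelism_lrt()`)
compares the shared-parameter model against a model with separate $b$
and $e$ (asymptotes always shared) by the Gaussian likelihood-ratio
statistic $\chi^2 = n \ln(\mathrm{RSS}_r / \mathrm{RSS}_f)$ on 2 df,
with the two 1-df intermediates also reported. Constant error variance
is assumed (the error model behind the published test is not stated).

A known limitation: this chi-square form is mildly anti-conservative on
small plates — on a synthetic 8-dilution duplicate plate (32 wells) the
null rejection rate at nominal 5% is about 8%, falling to about 6% at
200 wells. The test suite therefore checks calibration at the larger
well count, where the asymptotics hold; results from small single
plates should be read with that in mind.

Well-level QC (`qc_evaluate()`): strict quantifiable window 20–80
%B/B0 (the standard curve's linear portion), permissive 10–90% (90%
being the detection limit), duplicate CV $100\,s/\bar y$, rerun flag on
CV > 20% or a strict-window failure. `plate_cvs()` summarises intra-
and interplate precision from a shared control. Extraction efficiency
(94.1% ± 16%, carried over from the congeneric validation) is treated
as metadata and never applied as a concentration correction, matching
the original analysis choice of using all samples for distribution
fitting even outside the strict window.

## Synthetic data: what it does and does not emulate

`generator_config()` defaults are the study conditions: 6 females and
18 males per naive panel, naive lognormal parameters (2.46, 0.29) and
(5.69, 0.53), challenged (3.45, 0.68) and (6.54, 0.85); FSH shifts
equal to the challenged-minus-naive meanlog differences (0.99 female,
0.85 male — both sexes rise, no differential response, matching the
observed parallel increase); and log-scale pairing noise SD 0.6,
chosen once as consistent with the naive-to-challenged widening of
sdlog under independent noise. Wild cohorts are two-component mixture
draws with the latent sex kept in a clearly named `latent_sex` column
that the classifier path never reads. Plates are twofold dilution
series with Gaussian response noise.

The generators deliberately do **not** simulate assay-level measurement
error on testosterone (concentrations are drawn directly from the
sex-specific distributions), nor clutch or maternal random effects —
possible maternal influences on hatchling testosterone are discussed in
the field but no generative form has been established, so none is
invented here. Passing tests therefore demonstrate the statistical
machinery under the stated model, not robustness to assay error or
family structure in real cohorts.

## Problem sizes and numerical choices in the test suite

The suite runs everything at sizes chosen to make sampling error
negligible relative to each tolerance while keeping the default run
fast: threshold reproduction is exact and instant; oracle-equivalence
Monte Carlo uses $10^5$ replicates per sex (3-SE tolerance);
calibration of the interaction and parallelism null distributions uses
1,000 simulated datasets each; bootstrap coverage uses 300 outer
replicates of n = 200 samples at 1,000 bootstrap iterations.
Stochastic acceptance checks fix their seeds; the empirical-range
robustness check summarises five replicate Monte Carlo runs by their
median because its expected misidentification count per run is ~0.1 in
10,000 (a single run occasionally reports 0.01%, the typical run 0.00%).

## Limitations

* The density-ratio rule implies equal priors; applying it where the
  population sex ratio is known to be skewed requires reweighting.
* Fitted parameters may shift between populations; thresholds derived
  from one captive panel are a tool, not a universal constant.
* Sub-detection concentrations are retained as reported rather than
  treated by censored likelihoods.
* Mixture fitting of unknown-sex cohorts is out of scope; unknowns are
  assigned, not used to refit the distributions.
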