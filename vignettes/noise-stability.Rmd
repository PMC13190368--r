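---
title: "Measurement models for the noise stability of automatic item generators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models for the noise stability of automatic item generators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automatic item generation (AIG) builds test items from templates by varying
two kinds of elements: *radicals*, structural features assumed to drive item
parameters such as difficulty (here, three visual-load levels of a figural
short-term-memory task), and *incidentals*, surface features assumed to be
irrelevant (which emblem gets which frame, presentation order, distractor
choice). A generator is *noise stable* when incidental realizations neither
add between-item variance nor inflate residual variance. `noisestab`
implements the two classical-test-theory measurement models that make this
property estimable, one per sampling design:

* **cross-classified sampling** — every subject answers the same sampled
  incidental realizations, so subjects and incidentals are crossed and the
  incidental effect is estimable;
* **two-level sampling** — every subject receives a unique set of
  realizations (incidentals nested in subjects), which generalizes to a much
  larger incidental population but confounds incidental effects with noise.

## The models

For subject $s$, incidental realization $i$ and radical level $r$, the
cross-classified model is

$$Y_{si1} = \mu_1 + \eta_s + \beta_{i1} + \gamma_{si1}, \qquad
  Y_{sir} = \mu_r + \lambda_r \eta_s + \alpha_{sr} + \beta_{ir} +
  \gamma_{sir} \quad (r \neq 1),$$

with $\eta_s \sim N(0,\sigma_\eta^2)$ the ability at the reference level,
$\lambda_r$ free loadings ($\lambda_1 \equiv 1$ for identification, which
also resolves the sign of $\eta$), $(\alpha_{s2},\dots,\alpha_{sR}) \sim
N(0,\Sigma_\alpha)$ subject-level radical residuals, $\beta_{ir} \sim
N(0,\sigma_{\beta r}^2)$ incidental effects, and $\gamma_{sir} \sim
N(0,\sigma_{\gamma r}^2)$ a noise term in which the subject-incidental
interaction and measurement error are deliberately confounded (they are not
separable from single observations, and the package does not represent them
individually). Under two-level sampling the incidental stratum drops out and
$\beta$ is additionally absorbed into $\gamma$.

Because all latent components of an observation are orthogonal,

$$\sigma^2_{Y_{sir}} = \lambda_r^2\sigma_\eta^2 + \sigma_{\alpha r}^2 +
  \sigma_{\beta r}^2 + \sigma_{\gamma r}^2,$$

which `implied_moments()` reproduces exactly, along with every
within-subject and cross-subject covariance. Three relative variance
components summarize noise stability (`rcon`, `l2con`, `l1con`):

$$\mathrm{RCon}_r = \frac{\lambda_r^2\sigma_\eta^2}
  {\lambda_r^2\sigma_\eta^2 + \sigma_{\alpha r}^2}, \quad
  \mathrm{L2Con}_r = \frac{\lambda_r^2\sigma_\eta^2 + \sigma_{\alpha r}^2}
  {\lambda_r^2\sigma_\eta^2 + \sigma_{\alpha r}^2 + \sigma_{\beta r}^2},
  \quad
  \mathrm{L1Con}_r = \frac{\lambda_r^2\sigma_\eta^2 + \sigma_{\alpha r}^2}
  {\sigma^2_{Y_{sir}}}.$$

`l2con` is only meaningful under cross-classified sampling and refuses the
two-level design. A zero denominator raises a typed undefined-coefficient
error rather than returning 0/0. Per draw, $\mathrm{L1Con}_r \le
\mathrm{L2Con}_r$ and all coefficients lie in $[0,1]$; the suite asserts
both on every fitted model.

### Two summaries that differ in the third decimal

`consistency_from_draws()` evaluates each coefficient on every retained
posterior draw and reports the median with a 95% equal-tailed interval —
the summary credibility intervals require. `consistency_plugin()` instead
plugs a single parameter point (e.g. posterior medians) into the formulas.
A ratio of medians is not the median of ratios, so the two typically differ
in the third decimal; both are exposed because published tables usually
print the former while worked examples check the latter.

## Estimation

`fit_aig_model()` runs a blocked Gibbs sampler with conjugate full
conditionals (compiled; the update order is ability, radical-residual
block, incidental effects, intercepts, free loadings, then the variances
and the radical covariance). Priors default to normal$(0, 10^6)$ for
intercepts and free loadings, inverse-gamma$(0.001, 0.001)$ for scalar
variances, and inverse-Wishart($R$, identity) for $\Sigma_\alpha$ — the
standard weakly informative conjugate choices; all are overridable via
`priors()`. Defaults are 3 chains of 20{,}000 iterations with the first
half discarded as warm-up, a desk-scale budget that our convergence gate
(all potential scale reduction factors below 1.1, the conventional
criterion) comfortably passes on designs of a couple of hundred subjects;
`mcmc_settings()` exposes chains, length, warm-up fraction, thinning and
the seed, and an identical seed reproduces a fit bit for bit.

Chains start at per-level sample means, loadings 1, half the per-level
sample variance, and zero latents, overdispersed by chain-specific jitter
(additive normal, scale 0.5, for locations; log-normal, scale 0.5, for
variances) so the scale-reduction diagnostic is honest. Missing scores are
dropped from the likelihood (missing at random). A rare non-positive-definite
inverse-Wishart draw is retried with a small diagonal jitter and logged.
With an empty table (and explicit structural dimensions) the sampler
reproduces its priors, which the suite uses as a correctness check.

## The simulator

`simulate_responses()` draws data with exactly the statistical structure
the estimator assumes, in a fixed documented stream order (ability,
radical residuals, incidental effects, noise) from a single seed. Defaults
mirror the study conditions the models were built for: three radical
levels, three incidentals per level, a couple of hundred subjects
(208 cross-classified, 204 two-level in the published application). Scores
are continuous by default; `round_clip_0_20` optionally maps them to the
0–20 count range of a 20-emblem item, which biases moments slightly and is
meant for realism checks only, since the model treats counts linearly. The
generator refuses positive incidental variance under two-level sampling —
the design cannot express it — unless `confound_beta = TRUE` folds it into
the noise, mirroring the confound in the real design. Latin-square
presentation orders (`latin_square_orders()`) are emitted as pure metadata:
order effects are not modeled, and the warm-up block always runs
easiest-to-hardest.

What the generator does *not* emulate: integer score granularity (unless
post-processed), floor/ceiling effects, order or practice effects, and
non-normal ability or noise distributions. Passing tests therefore
demonstrate internal consistency of simulator, estimator and
decomposition — not that real figural-memory data satisfy the linearity
and normality assumptions.

## Model criticism

`bppc()` performs posterior predictive checking with a likelihood-ratio
chi-square discrepancy: conditioning on the current draw's incidental
effects makes subjects independent multivariate normals over their item
slots, so each draw yields $\chi^2(\mathrm{data};\theta) = -2\log L$ minus
the same quantity under a saturated per-pattern mean/covariance fit.
Replicated data of identical design are simulated from the draw (incidental
effects held fixed) and $\Delta\chi^2 = \chi^2(\mathrm{obs}) -
\chi^2(\mathrm{rep})$ is recorded; the reported p-value is the fraction of
draws with $\chi^2(\mathrm{rep}) \ge \chi^2(\mathrm{obs})$, with 0.5 ideal
and both signs of the mean difference reported since conventions differ.
By default 500 evenly spaced retained draws are evaluated. The saturated
correction matters: without it, the fitted model approximately
trace-matches the empirical covariance and the check loses essentially all
power against structural misfit. Being a second-moment discrepancy, the
check is sensitive to violations of the implied mean and covariance
structure (for instance, one incidental with inflated noise, which the
equal-variance-within-level implication forbids) but nearly blind to pure
shape violations, such as a bimodal score distribution whose first two
moments the refitted model can absorb — a limitation shared by any
chi-square-based check, worth keeping in mind when interpreting a
comfortable p-value.

`intercept_contrasts()` summarizes per-draw differences of the level
difficulties $\mu_r - \mu_{r'}$; `cross_model_differences()` compares
parameters shared by two independently fitted models by randomly pairing
equal-length subsamples of their draws (seeded, without replacement).
`welch_t()`/`one_sample_t()` provide the supplementary frequentist tests
(two-sided, no multiplicity correction, matching the published analysis
practice); they deliberately ignore subject dependencies, so their
intervals are anticonservative — they supplement, never replace, the
posterior summaries.

## Numerical choices and problem sizes

* Posterior summaries are medians with 95% equal-tailed intervals
  (`stats::quantile` type 7), pooled across chains.
* The scale reduction factor uses the classic between/within ratio, floored
  at 1 (the raw formula can dip marginally below 1 when chains agree more
  than chance would have it).
* The derived radical-effect correlation is computed per draw and clipped
  to $[-1, 1]$ at floating tolerance.
* The reference level is configurable and defaults to the first (easiest)
  level, the natural standard when harder levels add cognitive operations.
* Identifiers are deterministic strings (`s0001`, `r2_i03`) so tables diff
  cleanly; the CSV schema (`subject_id,radical_level,incidental_id,score`,
  missing as empty field) round-trips byte for byte.

The test suite exercises the estimator at the published design sizes
(208 subjects, 3 incidentals per level, 3 chains of 20{,}000 iterations for
the ten-replicate coverage study) and at reduced sizes chosen for quick
iteration elsewhere: 3 chains of 6{,}000 iterations for the predictive-check
calibration study and the end-to-end pipeline runs, 200 subjects with 8
incidentals per level for the balanced-ANOVA cross-check, 100{,}000
subjects for moment conservation, and 24 small two-level replicates for
simulation-based calibration. These sizes are the package's own trade-off
between Monte-Carlo resolution and iteration speed.

## Limitations

The models are linear-normal: ordered-categorical, Poisson-count and
reaction-time variants, random radical effects, and two-way incidental
sampling are out of scope. Only tolerance-level agreement with the
published posterior summaries can be expected, because the exact prior
specification and the discrepancy function of the original (closed-source)
estimation software are not reproducible from the publication; the package
therefore validates itself against independent statistical oracles —
closed-form moment estimators on balanced designs, coverage and
simulation-based-calibration studies, and the plug-in worked examples.
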