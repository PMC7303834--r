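---
title: "Distributed regression without pooling patient records: models, protocol, and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed regression without pooling patient records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dranet)
```

## The problem

In a horizontally partitioned data network each data partner holds every
variable for a distinct set of patients, and governance forbids moving
individual-level rows to a central location. Multivariable regression,
however, only needs the data through sums over subjects. `dranet`
exploits this: data partners compute summary-level intermediate
statistics on their own rows, an analysis center aggregates them,
updates the model, and iterates. The result is *mathematically
identical* to the pooled analysis — not an approximation, not a
meta-analysis of site-level estimates — and the package treats that
identity as its primary verification surface: every release-level check
compares a distributed run against a pooled reference fit of the same
rows.

## Models and exchanged statistics

All three families share one design-matrix convention, fixed entirely by
the model specification (`dra_spec()`): an intercept first (omitted for
the Cox family, whose partial likelihood has none), then covariates in
declared order, each categorical covariate expanding to one indicator
per non-reference level in declared level order. Because the layout
never depends on observed data, every site produces the same columns and
site contributions are elementwise-additive. The reference level is the
first declared level; a value outside the declared levels is a schema
error naming the site, column, and value, rather than a silently
re-fitted contrast.

**Linear regression** is solved in closed form from the aggregated
moments (n, XᵀX, Xᵀy, yᵀy, Σy). The protocol has exactly two rounds:
one for estimates and standard errors, one in which sites evaluate
residual error sums at the returned β̂ for the fit statistics
(R², AIC, Sawa's BIC, Schwarz's BIC, in the conventions of classical
least-squares software: AIC = n·log(SSE/n) + 2p, etc.). The residual
(second-round) SSE is used for the fit statistics because it is the
numerically preferable form near exact fits; the moment form
yᵀy − β̂ᵀXᵀy backs the first-round standard errors.

Sawa's BIC needs an error-variance estimate. The statistic is defined as
n·log(SSE/n) + 2(p+2)q − 2q² with q = n·σ̂²/SSE; `dranet` defaults to the
unbiased σ̂² = SSE/(n−p) (so q = n/(n−p)), which reproduces the
Sawa−AIC gap that full-model least-squares reports print; a documented
switch (`sawa_sigma2 = "mle"`) selects σ̂² = SSE/n, under which the
statistic degenerates to AIC + 2.

**Logistic regression** runs distributed iteratively reweighted least
squares from β = 0: sites return the score Xᵀ(y − μ) and information
XᵀWX at the current β, the center takes the Newton step. Convergence is
declared when the *maximum absolute change* in the coefficient vector
falls below ε (default 0.01, the convention of the standard regression
procedures this protocol mirrors), with a cap of 25 iterations;
non-convergence is reported with a warning and a `converged = FALSE`
flag, never silently accepted. The maximum-absolute-change metric was
chosen over relative-change or gradient criteria for transparency and
site-independence. Standard errors and the log likelihood are evaluated
in a final diagnostics round *at the converged estimates*, so reported
SEs correspond to the reported β̂. Note that ε = 0.01 targets protocol
equivalence, not high-precision maximum likelihood: when an external
oracle (such as `glm`) is compared at 1e-8 level, the tests tighten ε,
which is an ordinary specification parameter.

**Cox regression** runs distributed Newton–Raphson on the partial
likelihood with either the Efron (default) or Breslow tie correction.
A preliminary round merges the sites' distinct event times into a
global grid that is then shared with all sites, so at-risk sums can be
evaluated at event times observed only elsewhere. This leaks the
network's event times (a far weaker disclosure than patient rows, but a
disclosure); deployments that cannot accept it would need a different
decomposition. Per grid time t, sites send S₀, S₁, S₂ (the
exp(xβ)-weighted risk-set sums; S₂ travels as its lower triangle) and
the event-side sums d_t, s_t, S₀ᴰ, S₁ᴰ, S₂ᴰ. Risk sets use the
convention that a subject censored at exactly t is still at risk at t.
Because the aggregated sums equal the pooled sums exactly, events tied
across sites form a single tie group, and the distributed Efron result
equals the pooled Efron result — a property the test suite checks
explicitly on cohorts engineered to have cross-site ties. Plain Newton
steps are used, with no step-halving: divergence (e.g. monotone
likelihood) surfaces through the iteration cap. The 25-iteration cap
with quadratically convergent Newton updates makes this a deliberate
simplicity/robustness trade-off, and the log-partial-likelihood path is
recorded so a non-increasing step is visible.

The baseline survival curve uses the Breslow cumulative hazard
H₀(t) = Σ_{t_j ≤ t} d_j/S₀(t_j) at the final β̂, regardless of the tie
method used for estimation, evaluated at the mean covariate vector of
the patients with events (computed distributively as Σ_t s_t / D). The
median is read off the step function without interpolation (smallest
grid time with S ≤ 0.5; `NA` if never reached). Matching the
product-limit-style Efron baseline of some survival software exactly is
out of scope and documented as such.

**Binned diagnostics.** Individual predicted probabilities never leave a
site. Each site sorts its predictions ascending (stable ties), groups
consecutive runs of `roc_bin_size` (default 6) records, and ships per
bin only the mean prediction and the event/non-event counts; a final
partial bin keeps its true size so counts conserve. The center merges
all bins, collapses equal means into one operating point, and traces the
ROC curve with trapezoidal AUC. With bin size 1 this is exactly the
pairwise-concordance AUC (ties counted ½); with bin size 6 the error is
bounded empirically at well under 0.01 on cohorts of a few thousand
(about 8×10⁻⁶ at n = 5452 in the acceptance run). The
Hosmer–Lemeshow test partitions the merged bins into `hl_groups`
(default 10) risk-ordered groups at cumulative-count boundaries nearest
n·k/10, with expected counts from the bin means (individual predictions
being unavailable by design) and df = groups − 2 = 8.

## The file protocol

The orchestration mirrors an automatable file-transfer workflow: the
center writes a numbered directive file (instruction ∈
{compute_intermediates, compute_diagnostics, stop}, iteration index,
current β, shared event grid when relevant, and a digest of the model
specification), then a zero-byte `<name>.trigger`; partners poll their
inbox, compute, and reply with a payload file plus trigger. Payload
files are a one-line JSON manifest over delimited numeric blocks printed
with 17 significant digits, so every double survives the text
round-trip bit-exactly — the in-process engine and the file-based engine
produce *identical* fitted models, which the tests assert with
`identical()`. Directives with an already-processed sequence number are
stale: logged and ignored. Malformed inputs produce error files (from
partners) or parse errors naming the node and round (at the center),
never silent zero-fills. Partners re-deliver nothing on their own; the
center owns the iteration.

Aggregation sorts payloads by site id before summing, so results are
independent of arrival order and of partner process scheduling.
Transfer directories can be audited after a run (`dra_audit_workdir()`):
every file must validate against one of the protocol schemas, which is
how the no-row-level-data invariant is checked mechanically. Timing
records (download, compute, upload, transfer per node and round) are
collected in a transfer log and reduced by `summarize_timings()` to
mean ± SE per node class and step. Wall-clock values obviously depend on
hardware and transport; the instrumentation, not any particular number,
is the deliverable.

Polling uses a small sleep interval rather than OS-specific file-watch
APIs, for portability; the interval and a per-round collection timeout
(default 120 s) are configurable. The center aborts with a per-node
status when a round times out.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a three-site bariatric
surgery cohort: per-site sizes default to 1706/2728/1018 (total 5452);
covariates are age ~ Uniform(18, 79), baseline BMI ~ Normal(45, 7)
truncated at 35, six Poisson count covariates (comorbidity score mean 1,
ambulatory visits 8, other ambulatory 4, inpatient 0.3, non-acute 0.05,
ED visits 1, days-since-measurement 30), 6-level race (reference white,
majority 60%), 78% female, 6-level surgery year, Bernoulli(0.18)
exposure, and the site indicator as an ordinary covariate. One covariate
draw per subject feeds all three outcomes: a continuous outcome
xᵀβ + Normal(0, 2), a binary outcome Bernoulli(expit(xᵀβ)), and a
proportional-hazards Weibull event time (shape 1.2, baseline scale
0.00264 — chosen so roughly three quarters of subjects reach the event
within the 365-day administrative censoring window, echoing the 59–80%
outcome rates typical of such cohorts). True coefficient vectors default
to magnitudes typical of published bariatric analyses and are fully
configurable.

Event times are rounded *up* to whole days by default. This is
deliberate: integer days produce heavy ties within and across sites
(well over half of events share a day at n ≈ 2000), which is the hardest
path for the Efron correction and the cross-site tie-pooling logic. A
`round_days = FALSE` switch produces tie-free continuous times, used to
verify that Efron and Breslow then coincide exactly. Per-site
substreams derive deterministically from one master seed, so cohorts are
byte-reproducible.

What the generator does *not* emulate: claims-data realism (enrollment
spans, coding noise), missing data, informative censoring, or
confounding calibrated to any real study. Passing tests therefore
demonstrate the correctness and equivalence of the computation, not
clinical validity on real claims data.

## Numerical design choices

- **Equilibrated, centered solves.** The linear normal equations are
  solved through the corrected (mean-centered) SSCP matrix with Jacobi
  equilibration before Cholesky factorization, and the intercept row of
  the covariance is reconstituted analytically. Raw uncentered moment
  matrices with an intercept and covariates like BMI (mean ≈ 45,
  SD ≈ 7) are so ill-conditioned that factorization round-off, not the
  exchanged statistics, would dominate the distributed-vs-pooled
  difference. The same equilibration backs the IRLS and Newton solves.
- **What "machine precision equivalence" means quantitatively.** The
  only difference between the distributed and pooled computations is
  floating-point summation order. Measured on the default cohort, all
  logistic and Cox estimates and SEs agree to ~1e-14 or better, linear
  slopes to ~1e-13, and the linear intercept to a few times 1e-12 (its
  estimate is a linear combination of large covariate means, which
  amplifies ulp-level moment differences). Fit statistics of magnitude
  1e4–1e5 agree to 1–2 ulps, i.e. relatively ~1e-16, though that can be
  several times 1e-12 in absolute terms. The package's acceptance
  assertions encode exactly these scales: estimates/SEs < 1e-11
  absolute, fit statistics < 1e-12 relative, and everything orders of
  magnitude inside the 1e-6 bound conventionally used to declare a
  distributed deployment successful.
- **Singularities.** Moment and information matrices are guarded by a
  reciprocal-condition threshold of 1e-10; failures raise a collinearity
  or identifiability error naming the dependent columns (duplicated
  covariates, complete separation, monotone likelihood) instead of
  returning unstable estimates.
- **Degenerate inputs.** Zero-event networks, all-constant outcomes,
  empty sites, groups with expected counts of 0 or n in the calibration
  test, and curves never reaching S = 0.5 all produce typed errors or
  explicit `NA`s with a reason, never silent defaults.

## Problem sizes used in the test suite

Unit tests run on instances of 1–60 rows where brute-force oracles
(per-row accumulation, all-pairs concordance, central-difference
gradients) are exact and cheap. Equivalence and property tests use
three-site cohorts of 240–5452 subjects; partition invariance is swept
over k ∈ {1, 2, 3, 5} sites and three partition schemes; parameter
recovery uses a single 50 000-subject cohort, asserting every estimate
within three standard errors of its generating value. These sizes keep
the full suite under a minute while leaving each property's failure
modes (ties, separation, reordering noise) well exercised.

## Known limitations

- The shared event-time grid disclosure discussed above.
- No weights, offsets, robust/sandwich variances, stratification,
  time-varying covariates, or left truncation.
- No Firth correction: quasi-separated logistic cohorts (a rare
  covariate level with all-event or all-non-event outcomes) hit the
  iteration cap and are flagged as non-converged.
- The transport is a local shared directory standing in for a managed
  file-transfer network; there is no authentication or encryption. The
  transfer interface is a thin seam (`directive`/`payload` files) so a
  real transport could be substituted.
- Linear fit statistics assume the full model is the one fitted; no
  model-search variants of Sawa's BIC are provided.
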