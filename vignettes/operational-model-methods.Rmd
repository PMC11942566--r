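---
title: "Methods: fitting the operational model of allosterism to interaction data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitting the operational model of allosterism to interaction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allofit)
```

## The model and its assumptions

`allofit` analyses functional interaction experiments in which an
orthosteric agonist titration (extracellular Ca²⁺ acting on the CaSR is the
motivating case) is crossed with a concentration series of a candidate
allosteric modulator, and every response is expressed as a percentage of an
ionomycin control. The observational model is the operational model of
cooperative agonism and allosteric modulation, with one extension: the assay
buffer already contains agonist (0.1 mM Ca²⁺), so the model sees the applied
concentration [A] plus a fixed ambient term [C]. Writing

$$\Phi = ([A]+[C])^{n_B}\,(K_B + \alpha\beta [B]) + \tau_B [B]\, EC_{50}^{n_B},$$

the response is

$$E = \frac{E_m\,\Phi^{n_T}}{EC_{50}^{n_B n_T}(K_B+[B])^{n_T} + \Phi^{n_T}}.$$

Assumptions worth keeping in view:

- **Equilibrium, single functional read-out.** The model describes the
  peak-response surface, not the kinetics of the underlying fluorescence
  traces.
- **Combined cooperativity.** The affinity (α) and efficacy (β) components
  of cooperativity are not separately identifiable from a single functional
  assay, so the package carries only their product: `operational_params()`
  accepts `log_alpha` and `log_beta` but immediately sums them. All
  reporting is in terms of logαβ.
- **Transducer slope fixed at unity.** `n_T = 1` is the default and the
  standard analysis choice; the evaluator implements general `n_T` (the
  `nt` argument) so the reduction can be tested, but the fitter does not
  estimate it.
- **Log-scale estimation.** pK_B, logαβ, logτ_B and pEC₅₀ are estimated as
  logarithms, which makes their sampling distributions far closer to normal
  and their standard errors meaningful.

At `[B] = 0` and `n_T = 1` the model reduces exactly to a Hill function in
`[A]+[C]` with slope `n_B`; at `[A] = 0` and saturating `[B]` it tends to
`E_m τ_B/(1+τ_B)` — the intrinsic-agonism ceiling. Both identities are
enforced in the test suite to 1e-12 relative and used as oracles.

## Parameters, units, defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| `em` | maximal system response | % ionomycin | 100 |
| `pec50` | −log₁₀ agonist EC₅₀ | log M | 3.3 |
| `nb` | binding slope | — | 3 |
| `nt` | transducer slope | — | 1 (fixed) |
| `pkb` | −log₁₀ K_B | log M | — |
| `log_alpha_beta` | log₁₀ cooperativity | — | — |
| `log_tau_b` | log₁₀ intrinsic efficacy | — | — |
| `ambient_c` | buffer agonist | M | 1e-4 |

All concentrations are molar internally; micromolar appears only in display
(`kb_micromolar()`). Display rounding mirrors the conventional reporting
style: log-scale values to two decimals, linear-scale values to two
significant figures below 100, three digits at or above 100, and one
decimal below 1 — the rule that reproduces printed panel tables exactly.

Numerical evaluation of the model runs on the log scale (a log-sum-exp over
the two Φ terms and the denominator), because `nb * nt` powers of molar
concentrations overflow double precision long before the parameter bounds
are reached (binding slopes up to 6 are admitted; observed shared slopes of
3.5 are routine for steep Ca²⁺ curves).

## What the synthetic generator emulates — and what it does not

No raw plate data ship with the package; `simulate_dataset()` is the
first-class source of test material. `default_design()` encodes the assay
layout: modulator at 0, 0.03, 0.1, 0.3, 1, 3, 10 and 30 µM crossed with an
agonist series, duplicate technical reads, five independent experiments,
ambient agonist 0.1 mM, and homoscedastic Gaussian noise with SD 4 %
ionomycin added on the normalised scale, truncated at zero from below. The
agonist series is not part of the published layout, so the package chooses
an 11-point series — a zero-added (ambient-only) read plus ten
log-spaced concentrations from 10⁻⁵ to 10⁻¹·⁵ M — bracketing the
millimolar vehicle potencies (pEC₅₀ ≈ 3.0–3.6) that these assays show.
The zero-added agonist rows are what carry the intrinsic-agonism signal,
and the vehicle (modulator 0) column is required by the fitter.

A per-experiment multiplicative scale factor (`experiment_scale_sd`, SD 5 %
is a realistic setting) is available to emulate inter-experiment
variability, but the default is 0: the generator's stated noise model is
exactly additive Gaussian SD 4. The true split between intra- and
inter-experiment variance in real panels is unknown, so it is exposed as
configuration rather than asserted. Consequences to keep in mind when
reading test results: with jitter off, per-experiment SEMs from synthetic
panels are several-fold smaller than SEMs reported from real independent
experiments, so significance statements on synthetic panels are more
liberal than they would be on bench data. Passing recovery tests show the
estimator is consistent and calibrated under the stated noise; they do not
certify robustness to plate drift, heteroscedastic read noise or
liquid-handling artefacts, none of which are modelled.

`fixture_panel()` regenerates a seven-compound reference panel using each
compound's reported (pK_B, logαβ, logτ_B) as generating values and the
reported per-compound experiment counts; the two special rows are a
no-agonism compound (generating logτ_B = −5, i.e. τ_B ≈ 0) and a
deliberately near-neutral synthetic stand-in (logαβ = 0.02, τ_B ≈ 0) for an
interaction that defeats the operational model. Shared curve-shape
generating values are Em 100, pEC₅₀ 3.3, nB 3 — unreported in the original
analyses and chosen here as a steep, mid-range CaSR-like curve consistent
with a shared empirical Hill slope of 3.5.

## Global fitting

`fit_operational_global()` minimises the pooled sum of squared residuals
over every curve of a dataset simultaneously with six free parameters
(`em, pec50, nb, pkb, log_alpha_beta, log_tau_b`), Levenberg–Marquardt with
box bounds (`minpack.lm::nls.lm`). Choices that matter:

- **Bounds.** `em ∈ (0, 150]`, `nb ∈ [0.3, 6]` on the linear scale;
  `pec50 ∈ [1, 6]`, `pkb ∈ [2, 9]`, `logαβ ∈ [−2, 4]`, `logτ_B ∈ [−5, 3]`
  on the log scale. These bracket plausible assay behaviour; a parameter
  pressed against a bound is itself an ambiguity signal.
- **Multi-start.** The SSR surface is multimodal for weak modulators, so
  optimisation starts from a deterministic 3×3×3 grid over
  pK_B ∈ {4,5,6} × logαβ ∈ {0,1,2} × logτ_B ∈ {−1,0,1}, with the curve
  shape started at `em ≈ 1.05·max(y)`, pEC₅₀ 3.3, n_B 2.5. The best final
  SSR wins; ties break by grid order. A deterministic pre-screen
  (`n_best_starts`) can rank starts by initial SSR and polish only the
  best; the default polishes all 27.
- **Convergence.** Relative SSR tolerance 1e-10, at most 1000 iterations
  per start — fits on the default design converge in far fewer.
- **Standard errors** are asymptotic, from the curvature at the optimum;
  homoscedastic least squares, no robust loss (mirroring the reference
  software's default).
- **Weighting.** Unweighted SSR; every well counts equally.

`fit_operational_per_experiment()` runs the same fit per independent
experiment and reports mean ± SEM across converged experiments (at least
three required). This mode feeds the panel statistics, since SEM across
experiments is the reported uncertainty and the per-experiment estimates
are the exchangeable units for ANOVA.

## Identifiability and the "ND" path

Commercial curve-fitting software reports "ambiguous" fits by a proprietary
rule; `assess_identifiability()` uses a three-rule proxy, with thresholds in
`fit_config()` and no claim of equivalence:

1. any log-scale parameter SE above 1.0 log unit (or not computable);
2. any estimate at a box bound;
3. profile flatness — refitting with an allosteric parameter fixed 1 log
   unit from its optimum raises the SSR by less than 1 %.

A fit failing any rule is `ambiguous`; its estimates are withheld by
`coef()` and render as "ND" in panel tables. The near-neutral fixture
reproduces this path end-to-end.

Intrinsic efficacy gets one dedicated refinement. When a compound has no
intrinsic agonism the τ_B estimate does not converge to a value — the
likelihood is flat everywhere below some ceiling — and treating that as a
whole-fit failure would discard perfectly determined affinity and
cooperativity. After each global fit the package therefore performs a
zero-agonism refit (τ_B pinned at its floor, all else free): if the SSR
rises by less than the flatness threshold, logτ_B alone is reported as ND
and excluded from the ambiguity rules, while pK_B and logαβ stand. This is
the "no apparent agonism" ND, distinct from the "ambiguous fit" ND.

## The shared-slope fallback

When the operational model is ambiguous, `fit_hill_shared_slope()` fits
each modulator concentration's curve with its own floor, ceiling and pEC₅₀
while sharing a single Hill slope across all curves, jointly by least
squares. Per-curve pEC₅₀ values then support the descriptive statement such
data can still make — potency fold-shifts via `fold_shift()`, computed as
`10^(ΔpEC₅₀)`. The nested-model property (shared-slope SSR ≥ sum of
free-slope SSRs) is tested explicitly.

## Panel statistics and classification

`anova_dunnett()` runs, per parameter (three separate families — matching
the per-parameter reporting convention), a one-way ANOVA over compounds on
per-experiment estimates followed by Dunnett many-to-one comparisons
against the reference compound. Critical values come from the
multivariate-t distribution of the comparison statistics
(`multcomp::glht`), with the exact per-group n in the correlation structure
for unbalanced panels; the quasi-Monte-Carlo evaluation is seeded so
adjusted p-values are reproducible to ~1e-4. With two groups the adjusted
p-value collapses to the pooled t-test p-value — a degeneracy the tests
check to 1e-6 — and on null panels the familywise rejection rate sits at
the nominal 5 % (checked by simulation with 1000 panels).

`classify_profile()` labels compounds. Cooperativity is "positive" when the
lower confidence bound of logαβ exceeds 0; agonism is "detected" when the
logτ_B interval lies entirely above the no-agonism region logτ_B ≤ −1
(τ_B ≤ 0.1, under 9 % of `em` attainable without agonist). No numeric
agonism criterion is standard, and a CI-based rule was preferred over a
point-estimate cut because it lets imprecisely estimated low-τ compounds
("virtually devoid of agonism") fall on the pure-PAM side, as they should.
Intervals use the t distribution with n−1 degrees of freedom for
per-experiment summaries. Labels: ago-PAM (both), pure PAM (cooperativity
only, including τ_B ND), NAM-or-neutral (no positive cooperativity), ND
(ambiguous fit). Note that on low-variance synthetic panels the rule will
detect small but real generating agonism (e.g. logτ_B = −0.3 with SEM
0.1) that bench-scale SEMs would leave undetected; this is the rule
responding to precision, not a misclassification.

## Pipeline, provenance, determinism

`cmd_simulate()`, `cmd_fit()`, `cmd_compare()` (and `cmd_all()`) tie the
stages together on disk: long-format CSV datasets
(`compound,experiment,conc_A_M,conc_B_M,replicate,response_pct`), a YAML
provenance sidecar with the design and generating parameters, a long
fit-results table, and the panel report as CSV and Markdown. Every output
file's header carries the configuration hash (computed over the
analysis-relevant configuration, excluding the output path) and the master
seed; identical configurations give byte-identical datasets. All random
number use goes through seed-scoped draws that restore the caller's RNG
state.

## Problem sizes used in validation

The recovery experiments in the test suite and acceptance script use: 20
seeded five-experiment panels (880 observations each) at the reference
ago-PAM's generating values for the headline pK_B/logαβ recovery; 60
trimmed panels for bias and interval-coverage checks; an 8-curve, 528-point
sigmoid family for shared-slope recovery; 1000 simulated null panels for
the familywise error rate; and a 68,921-point exhaustive 0.05-log grid as
the independent oracle for the global optimum on a noiseless toy dataset.
These sizes give Monte-Carlo error comfortably inside the assertion
tolerances.

## Known limitations

- α and β are never separated; experiments designed to dissect
  affinity-versus-efficacy cooperativity need a binding assay and a
  different model.
- No kinetic modelling of fluorescence traces; only the peak-response
  surface.
- Homoscedastic noise is assumed by both generator and fitter; real plate
  data show response-dependent variance that neither models.
- The ambiguity rules are a pragmatic proxy, tuned to reproduce the
  qualitative ND outcomes of the reference panel; they are not a
  reimplementation of any proprietary criterion.
- Per-experiment mode needs ≥3 converged experiments; panels with chronic
  per-experiment ambiguity (weak-affinity compounds on narrow modulator
  ranges) fail over to the global-collated mode or the sigmoid fallback.
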