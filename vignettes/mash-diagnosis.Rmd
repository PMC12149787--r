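---
title: "Non-invasive MASH diagnosis from liver MRS and clinical biomarkers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive MASH diagnosis from liver MRS and clinical biomarkers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mashdx)
library(dplyr)
```

# The problem

Metabolic dysfunction-associated steatohepatitis (MASH) is the progressive
form of steatotic liver disease and is far more common after liver
transplantation (30-50%) than in the general population (~5.8%). The
reference diagnosis is biopsy, scored by the NAFLD activity score (NAS);
subjects split into non-steatosis (NoS, NAS <= 2), MASLD (NAS 3-4) and MASH
(NAS >= 5). `mashdx` implements a fully synthetic, testable version of the
non-invasive diagnostic pipeline: quantify liver fat by proton MR
spectroscopy, screen clinical/laboratory/MRS biomarkers by ROC, classify
MASH with a shallow decision tree, and restate the resulting operating
points as prevalence-adjusted accuracy and positive predictive value.

Because no subject-level data are available, the package ships a calibrated
generator for both cohorts and spectra; every downstream stage runs on data
the package can create from a seed.

# Spectrum model and quantification

A localized liver ^1^H spectrum is modelled as a sum of area-normalised
Lorentzian lines at the water position (4.7 ppm) and the lipid resonances at
0.9, 1.3, 1.6, 2.1, 2.4, 2.8, 4.2, 4.4 and 5.3 ppm (the 5.3 ppm vinylic
amplitude carries the 5.2 ppm contribution as one merged signal). The ester
signals at 4.2/4.4 ppm are fitted but excluded from all fat arithmetic; the
simulator gives them a small fixed share (2% of total lipid) precisely so
that the exclusion rule is exercised.

Quantification is a non-negative linear least-squares fit of the spectrum
against the basis lineshapes plus a constant baseline term
(`fit_spectrum()`). The baseline enters the non-negative solve: a
sign-unconstrained baseline is nearly collinear with the summed Lorentzian
tails and roughly doubles the amplitude noise, so the constrained form is
both the simpler and the better-conditioned choice. Fitted amplitudes are
integrated intensities.

Amplitudes measured at echo time TE are extrapolated to TE = 0 by
`t2_correct()`, multiplying by exp(TE/T2) with the fixed relaxation model
(water 27 ms, lipids 60 ms). A TE series (30, 50, 68, 135, 180, 270 ms) can
instead be fitted mono-exponentially on the log scale (`estimate_t2()`); the
fixed values are used as a fallback whenever the estimate's relative
standard error exceeds 30% (configurable), mirroring practice with unstable
in-vivo decay fits.

From the corrected amplitudes, with denominator
D = Lip09+Lip13+Lip16+Lip21+Lip24+Lip28+Lip53:

* fat fraction `FF% = 100 I_F / (I_F + I_W)` with I_F = D;
* `f_SI = (Lip09+Lip13+Lip16+Lip24)/D` (saturated),
  `f_UI = (Lip21/2 + Lip28)/D` (unsaturated),
  `f_PUI = Lip28/D` (polyunsaturated).

The closure identity `f_SI + (Lip21+Lip28+Lip53)/D = 1` holds to machine
precision by construction; the factor Lip21/2 is implemented exactly as the
definitions state. Relative lipid intensities use the same seven-signal
denominator (whether the source figures include the ester signals is not
stated; the package documents and uses the D convention).

## Simulator conventions

* Lineshape: Lorentzian; FWHM 0.10 ppm for lipids and 0.14 ppm for water at
  3 T; grid of 2048 points over 0-6 ppm.
* Amplitude solve: water fixed at 100 a.u.; lipid amplitudes are solved in
  closed form so that noiseless quantification returns exactly the requested
  FF and hydrogen fractions. Fractions are feasible iff
  `f_PUI <= f_UI` and `f_SI + 2 f_UI - f_PUI <= 1`; infeasible targets are
  rejected with a diagnostic. The saturated pool is distributed over
  Lip09/Lip13/Lip16/Lip24 as 12/72/9/7%, the methylene-dominant pattern of
  liver triglyceride.
* Noise: white Gaussian on the real spectrum only — no phase, baseline or
  eddy-current artifacts. `snr` is the ratio of the water amplitude
  (integrated intensity at the spectrum's TE, i.e. the quantity the fit
  estimates) to the per-point noise SD. Under this convention the simulator
  plus fitter recover FF within ±0.5 percentage points at snr = 50 across
  the 1-30% range, the precision target the pipeline assumes.
* Water suppression is not simulated; water and lipids are quantified from
  the same spectrum.

# Synthetic cohort generator

The generator reproduces the published three-group summary structure:
90 NoS, 20 MASLD and 17 MASH subjects, 23 variables summarised as median
(Q1-Q3) per group. Marginals are solved from those three numbers:

* log-normal for strictly positive skewed variables
  (mu = ln median, sigma = (ln Q3 - ln Q1)/(2 z_{0.75}));
* normal truncated at zero for near-symmetric ones (age, BMI, HbA1c, QUICKI
  and f_SI — the last two are bounded indices whose quartiles are nearly
  symmetric, where a log-normal fit would distort the upper tail).

Dependence is a Gaussian copula on a Spearman rank-correlation matrix
(converted to the latent Pearson scale by r = 2 sin(pi rho/6)). The default
targets couple FF at +0.5 with insulinemia, C-peptide, elastography, waist
and BMI, +0.3 within the metabolic block, -0.6 with f_UI and f_PUI, and
+0.6 between f_UI and f_PUI. These pairwise targets are jointly infeasible
— no correlation matrix attains all of them — so the assembled matrix is
projected to the nearest correlation matrix (alternating eigenvalue
clipping with unit-diagonal restoration); the realized default is e.g.
FF-insulinemia 0.449 and FF-f_UI -0.54. User-supplied matrices are not
projected: a non-PSD input is rejected, as are disordered quartiles.

One published quartile is corrected in the defaults: the MASLD bilirubin
upper quartile reads 7.23 in the source, below its own median; the value
17.23 (the evident transposition) is used.

Triglycerides are screened in the published ROC table but have no published
group summaries, so the default generator omits them; callers can append a
summary row to include them.

What the generator deliberately does not emulate: imaging, voxel placement,
biopsy variability, longitudinal repeat examinations, missing-data
patterns, and any real inter-variable correlation structure (the copula
targets are stated assumptions, not measured values). Passing tests
therefore demonstrate correctness of the *analysis machinery* under a
plausible data-generating process, not clinical performance on real
patients.

# ROC screening

`roc_curve()` builds the empirical curve over thresholds at midpoints
between consecutive distinct values plus infinite endpoints;
classification is strict (`>` or `<`), with the direction chosen per
variable so the AUC is at least 0.5 and reported alongside the cut-off.
AUC is computed by the rank (Mann-Whitney) statistic with ties counted one
half, which equals the trapezoidal area under the curve exactly — both
routes are exposed and their agreement is a tested invariant. Youden's
index (sensitivity + specificity - 100) selects the operating point; ties
are broken toward the more sensitive cut-off. `screen_variables()` runs
per-variable complete-case ROC against a group contrast (primary: MASH vs
NoS+MASLD) and flags variables with AUC < 0.7 as excluded, reporting the
per-variable n after missing-value removal.

# Decision tree

`grow_tree()` is a recursive partitioner in the JMP style: every candidate
threshold of every feature is scored by the likelihood-ratio statistic
G^2 = 2 sum O ln(O/E) on the split-by-outcome 2x2 table, with p from
chi-square(1) and LogWorth = -log10(p). A split is retained only when its
LogWorth reaches 1.3 (p <= 0.05); the tree also stops below 5 records per
node or beyond 4 levels (all configurable). Records equal to a threshold go
to the <= side; ties in G^2 go to the smaller threshold; missing values are
excluded at the node during search and routed to the larger child (flagged)
during prediction. Variable importance (`column_contributions()`) is each
feature's share of the summed G^2 over retained splits.

Two deliberate interpretation choices:

* The source describes its statistic as "G^2 (Pearson chi-squared)"; these
  differ. G^2 conventionally denotes the likelihood-ratio statistic, which
  is what the package computes; a Pearson X^2 option exists for comparison.
* "10-fold cross-validation with validation proportions of 30% and 50%" is
  not classical k-fold (which would hold out 10%). `cross_validate()`
  implements it as 10 repeated stratified Monte-Carlo splits at 70:30
  (primary) or 50:50, macro-averaging metrics over repetitions, which
  reproduces the stated proportions.

No multiplicity adjustment is applied over candidate thresholds within a
variable (JMP applies an internal adjustment it does not document); as a
consequence the returned split p-value is exact only in the
single-candidate case, and the chi-square reference is an asymptotic
approximation that over-rejects slightly when expected cell counts are
small.

# Diagnostic metrics at a target prevalence

From a (sensitivity, specificity) operating point, `performance_table()`
restates performance for a population with prevalence P:

* estimated accuracy = Sens P + Spec (1 - P) — linear in P;
* PPV = Sens P / [(1 - Spec)(1 - P) + Sens P] — strictly increasing in P.

The shipped scenarios are 40% (post-transplant) and 5.8% (general
population). Recomputing the published performance table from its own
printed sensitivity/specificity inputs reproduces the printed PPVs and
accuracies at their printed precision, with three caveats the tests encode:
two accuracy cells are internally inconsistent with their row inputs and
are excluded, and a few cells are truncated rather than rounded.

# Group comparisons and logistic confirmation

`compare_groups()` summarises a variable per group as median (Q1-Q3) and
gates between one-way ANOVA with Holm-Sidak step-down pairwise t tests and
Kruskal-Wallis with Holm-adjusted Dunn rank tests, using per-group
Shapiro-Wilk at alpha = 0.05 (the sources state both branches but not the
gate; a normality gate is the standard operationalisation).
`logistic_fit()` is maximum-likelihood binary logistic regression with Wald
inference and LogWorth per effect; `stepwise = TRUE` does forward selection
with a Wald entry criterion at 0.05 — one defensible reading of "stepwise
analysis". Quasi-complete separation is detected and flagged rather than
silently reported.

# Worked example

```{r example}
cohort <- simulate_cohort(cohort_config(), seed = 1)
count(cohort, group)

screen <- screen_variables(
  cohort,
  setdiff(names(cohort)[sapply(cohort, is.numeric)], "id")
)
head(select(screen, variable, auc, cutoff, direction, retained), 5)

tree <- grow_tree(cohort, screen$variable[screen$retained])
glance(tree)
column_contributions(tree)

cv <- cross_validate(cohort, screen$variable[screen$retained],
                     k = 10, train_fraction = 0.7, seed = 1)
cv$means

performance_table(tibble::tibble(
  method = "tree training",
  sensitivity = cv$means$sensitivity[cv$means$part == "training"],
  specificity = cv$means$specificity[cv$means$part == "training"]
))
```

`run_pipeline(pipeline_config(seed = 1, out_dir = "out"))` executes the
same flow end to end and writes the CSV/JSON/DOT bundle plus a run log from
which the run can be reproduced bit-identically.

# Numerical choices and problem sizes

* Quartile-to-parameter solves are closed-form and exact for the assumed
  families; copula sampling uses an eigendecomposition square root, so a
  positive semi-definite (including singular) matrix is acceptable.
* LogWorth is computed on the log scale
  (`-pchisq(g2, 1, lower.tail = FALSE, log.p = TRUE)/log(10)`) so extreme
  splits do not underflow to infinity.
* `estimate_t2()` fits on ln(I), drops non-positive amplitudes with a
  warning, and declares slopes >= 0 non-physical (T2 = Inf).
* Degenerate inputs error early with informative messages: both
  intensities zero in `compute_ff()`, all-zero lipid amplitudes in
  `compute_fractions()`, single-class labels in ROC and confusion metrics,
  constant variables in `best_split()` (no candidate split).
* Repeated-simulation checks in the test suite use 100-200 replicate
  cohorts or spectra and 2000-3000 null replicates — sizes at which
  Monte-Carlo error is a few tenths of a percent while the full suite runs
  in minutes.

# Known limitations

* The spectral model is deliberately minimal: no phase errors, frequency
  drift, baseline roll or water-suppression residuals, so quantification
  error on real spectra will exceed the synthetic round-trip error.
* The tree mimics the G^2/LogWorth rules but not JMP's undocumented
  internal p-value adjustment, so thresholds and LogWorths can differ from
  JMP output on identical data.
* Published real-data results (e.g. an FF AUC of 0.9561 or logistic
  LogWorths) are qualitative anchors only; with the original cohort
  unavailable, the package's numbers are synthetic analogues whose
  agreement is expected in distribution, not digit by digit.
* Under the calibrated group summaries the best-split FF threshold has
  substantial sampling spread (the 17-subject MASH group's lower quartile
  sits near 9%, so the empirical optimum oscillates between the NoS-MASH
  and MASLD-tail boundaries); its central tendency, not its per-seed
  value, matches the published 5.3.
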