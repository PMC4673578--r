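---
title: "Dual-marker GFR estimation: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-marker GFR estimation: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lundgfr)
```

## The estimation problem

Glomerular filtration rate cannot be measured directly; invasive clearance
of an exogenous tracer is the gold standard but is slow, costly and carries
risk, so routine care relies on prediction equations over endogenous
markers. The two markers in clinical use fail in *different, identifiable*
situations. Plasma creatinine is produced by muscle: every creatinine-based
equation implicitly assumes the mean muscle mass of a person of the
patient's age, sex and ethnicity, and is wrong exactly when that assumption
is wrong (paralysis, malnutrition, body-building, ageing-related muscle
loss). Plasma cystatin C is nearly muscle-independent but its synthesis is
increased by moderate-to-high doses of glucocorticoids.

`lundgfr` implements a strategy that turns this complementarity into an
internal quality check: estimate GFR with one equation per marker,
compare, and let agreement validate both. Three routes follow from a
discordant pair — trust the marker the clinical context does not
invalidate, or, when nothing explains the discrepancy, measure.

## The decision procedure

For estimates $a$ (cystatin-based) and $b$ (creatinine-based), both in
mL/min/1.73 m², agreement is judged by the symmetric relative difference

$$d = \frac{|a-b|}{(a+b)/2},$$

against a limit $L$. The procedure is:

1. $d \le L$: **USE_MEAN** — accept $(a+b)/2$.
2. $d > L$ and only muscle-mass flags present: **USE_CYSTATIN**.
3. $d > L$ and only a glucocorticoid flag present: **USE_CREATININE**.
4. $d > L$ otherwise (no flag, or both classes): **GOLD_STANDARD_REQUIRED**.

Choices that the underlying strategy leaves open, and how this package
resolves them:

* **Agreement metric.** "Agreement within specified limits" is made concrete
  as the symmetric relative difference above. It is dimensionless, symmetric
  in the two estimates, and commensurate with the ±30% (P30) accuracy idiom
  the field uses; the boundary $d = L$ counts as concordant.
* **Limits.** $L = 0.30$ in the general context; $L = 0.10$ when the
  estimate will be used for dosing drugs cleared by the kidneys, where a
  higher degree of agreement — and thus accuracy — is demanded. Both are
  per-call parameters of `concordance_policy()`, mirroring a clinician's
  option to stipulate the required agreement per patient.
* **Flags are consulted only on discordance.** Concordance is treated as
  self-validating: in the concordant case the mean is accepted even for a
  flagged patient. A `strict_flags` switch (default off) lets invalidating
  flags veto the mean, for sites that prefer flags to dominate.
* **Both flag classes present → gold standard.** If muscle mass is abnormal
  *and* the patient is on high-dose glucocorticoids, neither single-marker
  estimate is defensible; the engine fails safe.
* **Anchoring is permitted only after USE_MEAN.** A concordant decision ties
  a reliable GFR value to the patient's creatinine level; a flag-resolved
  single-marker decision does not validate that link, so `make_anchor()`
  refuses it.
* **Monitoring scales by the anchored equation.** Follow-up GFR is
  `gfr_ref · f(new_creatinine, new_age) / f(creatinine_ref, age_ref)` with
  $f$ the anchored creatinine equation at the patient's sex/population —
  not raw $1/\mathrm{creatinine}$ proportionality — so monitoring stays
  consistent with the equation family (for MDRD-like forms this reduces to
  the pure power law $\mathrm{crea}^{-1.154}$). A `MUSCLE_MASS_CHANGED`
  flag at follow-up signals a classed re-evaluation-required condition:
  anchors are immutable values here, so "invalidation" means the caller
  discards the anchor and repeats the dual-marker strategy.

## The equation registry

The strategy requires no particular prediction equations, so equations are
data: a registry of specifications (functional form + coefficients + age
range + required fields), serialisable to YAML/JSON. Four forms cover the
families in clinical use: `power_law_cystatin`
($A\,C^{-B}$ with optional pediatric multiplier), `mdrd_like`
($c_0\,(\mathrm{Cr}/88.4)^{e_1}\mathrm{age}^{e_2}$ times sex and population
coefficients), `height_over_creatinine` (Counahan–Barratt-style pediatric),
and `piecewise_loglinear` (segments of $\log \mathrm{GFR}$ linear in
creatinine and $\log$ creatinine with global age terms, covering
Lund–Malmö-style equations).

Shipped defaults (all overridable): cystatin power law $A = 84.69$,
$B = 1.680$, ×1.384 below age 14; IDMS-traceable MDRD
($c_0 = 175$, $e_1 = -1.154$, $e_2 = -0.203$, female 0.742, black 1.212,
and a variant carrying the Japanese-specific coefficient 0.763);
Counahan–Barratt $k = 0.43$ for ages 1–18. These coefficients come from the
primary literature on each equation, not from the strategy itself — sites
should select equations matched to their population and assay calibration.
No Lund–Malmö coefficients are shipped: inventing defaults silently would
be worse than requiring them by configuration.

Conventions fixed for determinism: age ranges are inclusive at the lower
bound and exclusive at the upper; the pediatric cutoff compares with strict
`<`; creatinine enters the interface in μmol/L only, with the single
constant 88.4 applied internally where a form is defined on mg/dL; missing
optional fields never default — they make an equation inapplicable, which
the decision engine reports rather than guesses around.

## Inversion and numerical choices

The synthetic-cohort generator manufactures marker levels by inverting the
registered equations at the true GFR. All four forms are strictly
decreasing in their marker, so the inverse exists; it is analytic for the
power-law, MDRD-like and height forms, and computed by bisection
(`uniroot` on the log scale, tolerance 1e−13, bracket
$[10^{-4}, 10^{6}]$ μmol/L) for the piecewise form. Round-trip error
forward(invert(g))/g − 1 is verified below 1e−9 across GFR 5–150 for every
built-in equation (in practice it is at machine precision for the analytic
inverses).

## The synthetic cohort: what it emulates

Per patient: true GFR uniform on [10, 120] mL/min/1.73 m² (spanning severe
renal failure to normal function), age uniform on [20, 80] (inside the
adult validity range of the default creatinine equation), 50% female.
Confounders are mechanistic and multiplicative, matching how the markers
are produced physiologically:

* **Muscle factor $M$** multiplies creatinine only. Background biological
  variation is lognormal with sdlog 0.15; with probability
  `p_muscle_abnormal` the patient is clinically abnormal and $M$ is forced
  to `muscle_abnormal_factor` (0.5 for the low-muscle scenario, 2.0 for
  high) and flagged.
* **Steroid factor $G$** multiplies cystatin C only, for treated patients
  (probability `p_glucocorticoid`). The magnitude of glucocorticoid-induced
  cystatin elevation is not well quantified; the default $G = 2$ is a
  moderate-to-high-dose scenario value, comfortably below the up-to-13-fold
  elevations seen in anuric haemodialysis patients, and large enough that
  the induced bias ($G^{-1.68} \approx 0.31\times$) clearly exceeds the
  0.30 agreement limit — the scenario the arbitration rules exist for.
* **Assay noise** is multiplicative lognormal with meanlog 0 and sdlog
  $\log(1+\mathrm{cv})$ (defaults: CV 5% per assay). This
  parameterisation is used uniformly (rather than
  $\sqrt{\log(1+\mathrm{cv}^2)}$) because it is positivity-preserving,
  simple to invert analytically in tests, and indistinguishable at assay
  CVs (at CV 10% the two sdlogs differ by < 5%); its mean factor
  $e^{s^2/2}$ is within 0.5% of 1 at CV 10%, verified by a
  law-of-large-numbers test.
* **Gold-standard imprecision**: the simulated measured GFR is
  `true_gfr × lognormal(0, log(1+cv))` with CV 10% by default. A direct
  consequence, quantified by `scripts/acceptance.R`: two gold-standard
  measurements on the same stable patient agree within ±30% only ~97% of
  the time, so a prediction equation with P30 ≈ 90% against *measured* GFR
  is close to the theoretical ceiling.

Ground truth (true GFR, $M$, $G$, true flags, and the route the
deterministic confounders imply before assay noise) is returned beside the
panel, and the whole cohort is reproducible bitwise from its seed (one
private RNG stream; the caller's `.Random.seed` is untouched).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: calibration offsets between assays (a major
source of between-study equation disagreement), non-GFR determinants of
cystatin C other than glucocorticoids (thyroid dysfunction, inflammation),
diet and tubular secretion effects on creatinine, correlated errors between
the two assays, and longitudinal GFR trajectories. Recovery results on
synthetic cohorts validate the *logic and implementation* of the strategy,
not its clinical accuracy, which only patient cohorts with measured GFR
can establish.

## Validation set-up

The test suite checks, among others: exact agreement of the decision
engine with an independently written brute-force truth table over every
valid flag subset × concordance outcome (24 cases); strict monotonicity of
every registered equation on a 1000-point marker grid; inversion
round-trips; noise-free cohorts recovering true GFR identically through
both markers (n = 10 000); confounder scenarios routing 100% of patients to
the correct arm with exact single-marker recovery (n = 2 000 per scenario);
gold-standard repeatability against the closed-form lognormal-ratio
probability (n = 100 000, agreement within 0.5 percentage points); and the
mean estimator's P30 dominating each single marker under independent assay
noise at CV 20% (n = 100 000) — CV 20% is used for that property because at
routine assay CVs of ~5% all three estimators sit near 100% P30 and the
comparison has no power. These sizes keep the full suite under ~10 s while
leaving Monte-Carlo error far below every margin tested.

## Known limitations

* The package evaluates one decision per time point; it does not schedule
  gold-standard procedures, compute drug doses, or model longitudinal
  trends beyond anchor scaling.
* Equation applicability is guarded by age and field presence only;
  pregnancy, amputation and other situations that shift marker production
  must be handled by the caller through flags or equation choice.
* The flag vocabulary is deliberately minimal (two invalidating classes
  plus a monitoring flag); real clinical context is richer, and unlisted
  causes of discordance will correctly fall through to the gold-standard
  route.
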