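---
title: "Reconstructing HCN inhalation from paired cardiac blood cyanide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing HCN inhalation from paired cardiac blood cyanide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireCN)
```

## The forensic problem

Postmortem venous cyanide alone is a treacherous diagnostic: a victim
who inhales a very high HCN concentration can suffer respiratory arrest
within a fraction of a minute, before venous blood has equilibrated, and
present at autopsy with a deceptively low venous CN. During uptake the
arterial concentration leads the venous one, and the size of that lead
depends jointly on how concentrated the gas was and how long it was
breathed. Left cardiac blood approximates systemic arterial blood and
right cardiac blood venous blood, so the measured pair (L, R) is, in
effect, a two-point observation of the uptake trajectory. This package
reconstructs the exposure — constant inhaled concentration $C_a$ (ppm)
and inhalation time $T$ (min) — that best explains the pair under a
physiologically based pharmacokinetic (PBPK) model.

## The forward model and its assumptions

The model is a flow-limited compartmental mass balance: a
gas-exchange/arterial blood pool, a venous pool, and any number of
perfused tissues in parallel. State variables are *amounts* (µg), not
concentrations; concentrations are derived on output. This makes the
conservation identity — cumulative inhaled mass equals body burden plus
cumulative metabolized plus cumulative exhaled — exact at the level of
the differential equations, so the integrator can be audited against it
(`mass_balance_error()`; the suite requires closure to 1e-6 relative,
and the fixed-step RK4 solution closes to ~1e-15).

Assumptions, all deliberate simplifications:

* **Constant exposure, no post-exposure phase.** The inhaled air
  concentration is constant over $[0, T]$ and the simulation ends at
  $T$ (death). Real fire atmospheres fluctuate; postmortem
  redistribution (CN accumulated in lung tissue diffusing into the left
  atrium) is not modelled, though reading the "arterial" compartment as
  lung-plus-arterial-blood partially absorbs it.
* **All kinetics first-order.** Tissue exchange is
  perfusion-limited, detoxification to thiocyanate is a first-order
  rate per compartment. No saturable (Michaelis–Menten) metabolism, no
  methemoglobin binding, no CO co-exposure kinetics. Consequence: the
  system is linear and blood concentrations are exactly proportional to
  the inhaled concentration — a property the estimator exploits and the
  tests assert to 1e-9.
* **ppm → mg/L conversion** uses molar volume 24.45 L/mol (25 °C,
  1 atm), the industrial-hygiene convention; a temperature override
  recomputes it from the ideal-gas law. Blood µg/mL ≡ mg/L is used as
  an identity throughout.

## Parameters

`default_pbpk_params()` ships a **generic reference-human set**,
assembled once from standard physiological tables (Brown et al. 1997
style volumes and perfusion fractions) with cyanide-specific constants
at round literature-scale values:

| quantity | value | why |
|---|---|---|
| cardiac output | 6.2 L/min | resting adult reference |
| alveolar ventilation | 5.4 L/min | resting adult reference |
| blood:air partition | 200 | HCN is highly blood-soluble; literature-scale |
| tissue:blood partitions | 1.0 (0.25 fat) | CN distributes in water; lipid-poor |
| hepatic k_met | 0.35 /min | rhodanese detoxification; gives a blood half-life of tens of minutes |
| blood pools | 1.8 L arterial (incl. lung), 3.7 L venous | reference blood volume split |

This set is explicitly *non-canonical*: it is not an HCN-calibrated
published parameterisation, and absolute reconstructions depend on it.
What transfers across any all-first-order parameterisation of this
structure: the arterial > venous ordering with a widening early gap, the
dose-linearity, the monotone mapping from the L/R ratio to shorter
exposure times, and therefore the *ranking* of cases. What does not:
the absolute ppm and minute values of individual reconstructions, which
is why the acceptance suite's comparison against the packaged reference
reconstruction is expected to fail unless the matching calibration is
supplied via `read_pbpk_params()`. Ventilation is the single most
influential constant (it scales uptake directly; escape-level activity
could roughly triple it), followed by the arterial pool volume (it sets
how fast the arterial side saturates).

## The inverse problem

`estimate_exposure()` scans the full lattice — by default 1501
concentrations (0–18,000 ppm, step 12) × 601 times (0–30 min, step
0.05) — and minimises

$$\mathrm{SSE}(C_a, T) = (R - \hat C_{ven}(C_a, T))^2 +
                         (L - \hat C_{art}(C_a, T))^2 .$$

Design choices where the design was genuinely open:

* **Eligibility.** Only cases quantified in *both* chambers are
  inverted. A censored value (`ND`, `Trace`) has no number to fit;
  imputation would manufacture precision, so such cases raise an error
  rather than a guess.
* **Tie-breaking.** Lowest concentration first, then shortest time,
  with the number of tied lattice points reported. At $T = 0$ every
  concentration scores identically ($R^2 + L^2$), so a deterministic
  rule is not cosmetic; the all-zero measurement degenerates stably to
  (0 ppm, 0 min).
* **Factorisation.** One forward simulation serves all 601 times of a
  given concentration. Because the model is linear, one *reference*
  simulation serves all 1501 concentrations as well (`method =
  "linear"`, the default, ~0.1 s per case); `method = "exhaustive"`
  re-simulates per concentration and is kept as the brute-force oracle —
  the suite checks the two agree on 20 random cases.
* **Grouping thresholds.** `Ca_high_T_short` requires concentration
  ≥ 5000 ppm (inclusive) *and* time < 1 min (exclusive). Reference
  group tables in circulation occasionally include a sub-threshold case
  in the high group; the package applies the stated criterion uniformly
  and leaves discrepancies visible rather than special-casing them.
* **Sensitivity.** The ±15% assay uncertainty is propagated as the
  full 3 × 3 factorial of {−15%, 0, +15%} scalings of (R, L); its
  min/max bounds any subset convention, and the 9-row table is
  returned for inspection. The spread is nested in the perturbation
  size (checked at 5% vs 15%).

## Cohort statistics

* **Detection** = `Trace` or quantified in either chamber (i.e. at or
  above the 0.2 µg/mL LOD). On the packaged 29-case table this gives
  23/29 = 79.3%.
* **Trace values never enter arithmetic.** Below the LOQ there is no
  number; traces count for detection and sit below thresholds in zone
  classification, nothing else.
* **Poisoning zones** partition (COHb%, CN) at 50% and 1 µg/mL on
  right cardiac blood as the venous proxy; zone 2 (CN-dominant) is the
  forensically critical quadrant.
* **SCN comparison.** The group-wise right-vs-left thiocyanate test
  defaults to the unpaired pooled-variance Student t-test, which is the
  variant that reproduces the reference p-value on the packaged group
  table (p = 0.0040 on rounded inputs, within rounding of the reported
  0.0038); Welch and paired variants are provided. The paired variant
  is arguably the more natural design (two chambers of one body) and is
  a one-argument switch.
* Percentages are reported rounded half-up to one decimal; all CSV
  output carries full precision and rounding happens only in the
  printed report.

## The synthetic-cohort generator

`generate_cases()` emulates the *statistical shape* of a fire-death
case table: true exposures drawn log-uniformly over 50–16,000 ppm and
uniformly over 0.05–30 min (snapped to the search grid by default, so
that noiseless generation is exactly recoverable; off-grid draws
isolate quantisation error), forward-simulated arterial → left and
venous → right concentrations, multiplicative log-normal noise with the
central 95% interval spanning ±15% (a uniform ±15% option mirrors the
sensitivity-analysis convention), and censoring of the noisy values at
LOD 0.2 / LOQ 0.4 µg/mL. COHb% and SCN covariates are *descriptive*
draws spanning the observed ranges (with an optional right-chamber SCN
inflation in the high-exposure group so the group comparison has a
synthetic analogue) — they are knobs, not mechanism. What passing
recovery tests therefore show: the estimator inverts its own forward
model correctly under the stated noise and censoring. What they cannot
show: that the forward model, or any particular calibration of it,
matches real human toxicokinetics.

`recovery_experiment()` reports bias, RMSE, relative RMSE and the
group-confusion matrix; under zero noise with on-grid truths all errors
are exactly zero, and the error is monotone in the noise scale
(checked at 0.15 / 0.05 / 0).

## Numerical choices

* Fixed-step RK4 with `dt = 0.05` min lands outputs exactly on the
  0.05-min reporting grid — an adaptive solver would reintroduce
  interpolation error precisely where the objective is evaluated.
  `n_substeps` refines the internal step without moving the grid.
* Step-halving convergence is measured relative to the *solution
  scale* (sup norm): venous CN rises from zero like $t^3$, so a
  pointwise ratio at the first output step is ill-conditioned for any
  step size. Scale-normalised, halving changes the solution by ~3e-8.
* Degenerate inputs: zero-duration scenarios return the single-row
  zero state; empty eligible sets return empty results with warnings
  (not errors); non-finite states abort the integration with the
  failure time in the message.
* Seeds: the synthetic spec carries its seed; identical specs produce
  byte-identical tables.

## Problem sizes used by the test suite

The suite runs a three-tissue parameter set and reduced lattices
(21 × 31) for oracle-equivalence and recovery loops, full-scale
simulations for the conservation/convergence checks, and the full
1501 × 601 lattice for the packaged-cohort inversions; the whole suite
completes in well under a minute, the acceptance script in ~2 s.

## Known limitations

No methemoglobin scavenging, no CO interaction, no saturable
metabolism, no postmortem redistribution, constant exposure only, and a
generic default calibration (see above). Individual variation in body
weight, fat fraction and ventilation directly rescales estimates;
per-case parameter files are the intended mechanism for exploring that.
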