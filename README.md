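# fireCN

Forensic reconstruction of hydrogen cyanide (HCN) exposure in
fire-related deaths.

Fire victims inhale both carbon monoxide and HCN. CO poisoning is
routinely diagnosed from carboxyhemoglobin (COHb%), but cyanide is
measured far less often, and a single venous CN concentration can badly
understate the exposure: after a brief inhalation of a high HCN
concentration, respiratory arrest can occur before venous blood has had
time to load, leaving a low CN level in a victim who died of cyanide.
The arterial side, however, leads the venous side throughout uptake, so
the *pair* (left cardiac blood ≈ arterial, right cardiac blood ≈ venous)
carries information about both how concentrated the gas was and how long
it was breathed. `fireCN` turns that observation into a pipeline:

1. **Forward PBPK model** — a flow-limited, multi-compartment
   physiologically based pharmacokinetic model of CN during constant HCN
   inhalation. For compartment amounts \(A_i\) (µg), arterial/venous
   blood pools and tissues \(i\) with perfusion \(Q_i\), volume \(V_i\),
   tissue:blood partition \(P_i\) and first-order detoxification
   \(k_i\):

   - arterial: \(\dot A_{art} = Q_{alv}\,(C_{air} - C_{art}/P_{b:a}) + Q_{co}(C_{ven} - C_{art}) - k_{art}A_{art}\)
   - tissue: \(\dot A_i = Q_i\,(C_{art} - C_i/P_i) - k_i A_i\)
   - venous: \(\dot A_{ven} = \sum_i Q_i\,C_i/P_i - Q_{co}\,C_{ven} - k_{ven}A_{ven}\)

   with \(C_i = A_i/V_i\), inhaled air concentration \(C_{air}\)
   (mg/L, from ppm via the molar volume), alveolar ventilation
   \(Q_{alv}\), cardiac output \(Q_{co}\) and blood:air partition
   \(P_{b:a}\). Integration is classic fixed-step RK4 on the 0.05-min
   output grid; amounts-as-state makes the mass balance (inhaled =
   burden + metabolized + exhaled) close to solver precision.

2. **Inverse estimation** — an exhaustive grid search over inhaled
   concentration (0–18,000 ppm, step 12) and inhalation time (0–30 min,
   step 0.05) minimising
   \((R - \hat C_{ven})^2 + (L - \hat C_{art})^2\)
   for the measured right/left pair \((R, L)\), with deterministic
   tie-breaking, exposure-group classification
   (`Ca_high_T_short`: ≥ 5000 ppm and < 1 min; otherwise
   `Ca_low_T_long`) and a ±15% measurement-uncertainty sensitivity
   analysis (3 × 3 factorial on the two measurements).

3. **Cohort statistics** — censoring-aware parsing (`ND` below the
   0.2 µg/mL detection limit, `Trace` below the 0.4 µg/mL quantification
   limit), detection summary, COHb/CN poisoning-zone classification
   (thresholds 50% and 1 µg/mL on the venous proxy), left-vs-right CN
   dominance, and the right-vs-left thiocyanate (SCN) t-test within
   exposure groups.

4. **Synthetic cohorts** — a generator with the same statistical
   structure (forward-simulated exposures, multiplicative noise,
   LOD/LOQ censoring, covariates) for parameter-recovery experiments.

A packaged table of 29 fire-death autopsy cases
(`inst/extdata/fire_deaths_cohort.csv`) and its reference exposure
grouping drive the worked examples. The default PBPK parameter set is a
clearly-labelled *generic* reference-human construction
(`?default_pbpk_params`); any calibration can be supplied as YAML.

## Worked example

```r
library(fireCN)

cases <- fire_cohort()
cohort_report(cases, estimates = exposure_groups_reference())
```

```
Forensic cohort report
----------------------
  cases: 29
  CN detected (either chamber): 23 of 29 (79.3%)
  poisoning zones (right cardiac blood, 29 classifiable): zone1=10, zone2=3, zone3=11, zone4=5
  left > right CN: 13 of 13 doubly-quantified cases (100.0%)
  SCN range: 0.92-8.5 ug/mL
  all cases exceed 2.0% COHb
  SCN right vs left, Ca_high_T_short: mean 3.2 vs 2.12, t = 3.438 (df 14), p = 0.0040 [pooled]
  SCN right vs left, Ca_low_T_long: mean 2.5 vs 2.44, t = 0.098 (df 8), p = 0.9246 [pooled]
```

Reading: CN was detectable in 23 of 29 cases; three cases sit in zone 2
(COHb below 50% but CN at toxic levels — deaths a CO-only work-up would
misattribute); in every doubly-quantified case the left (arterial-side)
chamber exceeds the right, the signature of inhaled HCN gas; and in the
high-concentration/short-exposure group venous SCN significantly exceeds
arterial SCN (p = 0.0040, pooled t), consistent with rapid first-pass
detoxification during a brief, intense exposure.

Inverting a single case (right 0.48, left 2.7 µg/mL — a large
arterial excess, i.e. a short, concentrated exposure):

```r
p <- default_pbpk_params()
estimate_exposure(0.48, 2.7, p, case_id = "17")
#> exposure estimate [case 17]: 2664 ppm for 0.9 min (sse 0.0001667, 1 tie) -> Ca_low_T_long
sensitivity_analysis(0.48, 2.7, p, delta = 0.15, case_id = "17")
#> sensitivity (+/-15%) [case 17]: conc 2064..3264 ppm, time 0.75..1.15 min, group(s) Ca_low_T_long
```

Absolute estimates are calibration-dependent: with the generic
parameter set this case reconstructs to ~2700 ppm over ~1 min, and the
±15% assay uncertainty moves the concentration by roughly ±600 ppm.
The *ordering* across cases (large L/R ratio → shorter, more
concentrated exposure) is robust; see the methods vignette
(`vignettes/hcn-exposure-reconstruction.Rmd`) for what does and does not
transfer across parameter sets.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/firecn.R estimate --cases cases.csv --out estimates.csv
Rscript inst/cli/firecn.R synth --n 29 --seed 1 --out synth.csv --out-truth truth.csv
```

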