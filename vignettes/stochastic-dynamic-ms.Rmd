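---
title: "Stochastic-dynamic quantification of scan-level MS measurands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic-dynamic quantification of scan-level MS measurands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdms)
```

## The model

Classical quantitative mass spectrometry integrates the area of a peak —
over retention time or over the isotope shape — and regresses that area on
concentration. In complex matrices (biota extracts, sludge), at low analyte
concentration, and in the presence of tautomeric fragment ions and
cation-radical side channels, the peak shape mixes contributions of several
species and the area-based calibration degrades.

`sdms` implements an alternative that treats the per-scan intensity
\(I_i\) of one monitored measurand as a discrete random variable and
quantifies its *fluctuation* over short spans of scan time. For a span
\(i\) of consecutive scans, the variance-form diffusion parameter is

\[
D''_{SD,i} \;=\; 2.6388\times 10^{-17}\,
\bigl(\overline{I_i^2} - \overline{I_i}^{\,2}\bigr),
\qquad
D''_{SD,tot} \;=\; \sum_i D''_{SD,i},
\]

with the raw-moment (denominator \(n\)) population variance. The companion
amplitude form divides by the mean squared deviation and multiplies by the
amplitude \(A_i\) of a sine-squared temporal model,

\[
D'_{SD,i} \;=\; 1.3194\times 10^{-17}\, A_i \,
\frac{\overline{I_i^2}-\overline{I_i}^{\,2}}
     {\overline{(I-\overline{I})^2}},
\]

where \(A_i\) comes from fitting \((I-\langle I\rangle)^2 = f(t)\) with
the SineSqr model \(y = y_0 + A\sin^2\!\bigl(\pi (x-x_c)/w\bigr)\). The two
constants satisfy \(K_2 = 2K_1\) (asserted in code), which makes the two
forms coincide whenever the fitted curve's mean equals the sample variance
— exactly the case for a noiseless sine-squared deviation trace. Under
noise the two statistics separate, and the correlation between
\(D'_{SD,tot}\) and \(D''_{SD,tot}\) across series measures the error
contributed by the temporal fit (`d_prime_vs_dsecond()`).

Quantification regresses \(\ln D''_{SD}\) (or \(D''_{SD}\) itself) on
concentration (`calibrate()`). Two relations connect the measurements to
theory:

* the collision-energy intensity relation
  \(\overline{I}_{theor}^{\,q} = \tfrac12 (A_I^q/A_D^q)\, D''_{SD,tot}\),
  with \(A_D^q, A_I^q\) the SineSqr amplitudes of \(D'' = f(CE)\) and
  \(\langle I\rangle = f(CE)\) (`eq4_profile()`);
* the quantum-chemical diffusion parameter
  \(D_{QC} = \bigl(\prod \nu_i^0 / \prod \nu_i^s\bigr)
  e^{-\Delta H^\ddagger/(RT)}\) from ground-state and transition-state
  vibrational wavenumbers (`d_qc()`), whose linear correlation with the
  measured \(D''_{SD}\) over the fragment ions of one analyte is the
  structure-confirmation criterion (`correlate_structure()`,
  `assign_structures()`).

### Assumptions

* Scans are centroided; one intensity per scan enters a measurand series
  (the most intense in-window centroid).
* Fluctuations within a span are stationary enough for a single variance
  to be meaningful; spans are therefore *short* (default 5 scans) and the
  total is accumulated across spans rather than pooled.
* The squared-deviation trace is adequately described by one SineSqr arch
  per span; \(D'\) is only as good as that fit, which is the stated source
  of the \(D'\)–\(D''\) discrepancy.
* The constants \(1.3194\times10^{-17}\) and \(2.6388\times10^{-17}\) are
  applied verbatim to intensities in counts. Their physical provenance and
  unit bookkeeping are not derivable from first principles here; outputs
  are labelled cm²·s⁻¹ following the field's convention, and no intensity
  unit conversion is attempted. This is a documented limitation, not an
  endorsement of the absolute scale.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `span_length` | `span_spec()` | 5 scans | fluctuation window; ≥ 2 (≥ 4 for \(D'\)) |
| `no_match_policy` | `extract_window()` | `"zero"` | unmatched scans count as 0 intensity (`"skip"` omits them) |
| `tolerance` | `measurand_window()` | — | half-width of the closed m/z window, Thomson |
| `alpha` | `group_measurands()` | 0.05 | significance level of the Welch-t merge and the distinctness verdict |
| `gap` | `group_measurands()` | 0.2 Th | pre-split width: sorted m/z values separated by more than this start in different candidate groups |
| `denominator` | `d_sd_first()` | `"fitted"` | mean-squared-deviation estimate: time-average of the fitted SineSqr curve, or `"sample"` (ratio ≡ 1) |
| `seed`, `n_starts` | `fit_sinesqr()` | 1, 10 | deterministic multi-start schedule |
| `unit`, `temperature` | `qc_ion_model()` | hartree, 298.15 K | activation-enthalpy unit (gas constant follows) and temperature |
| `threshold` | `isotope_pattern()` | 1e-4 | prune relative abundance below this fraction of the base peak |

Choices made where the design was genuinely open:

* **\(D'\) denominator.** Taken as the same-span sample statistic, the
  denominator would cancel the numerator exactly and reduce \(D'\) to
  \(K_1 A_i\). The default instead uses the time-average of the *fitted*
  SineSqr curve over the span's scan times — a smooth estimate that
  coincides with the sample variance for noiseless traces but differs
  under noise, preserving the informative discrepancy between the two
  forms. The same-sample alternative remains selectable.
* **Span addressing.** Explicit span boundaries address 1-based positions
  within an intensity series (the R convention); scan *indices* in the CSV
  dialect are stored as given (0-based in the shipped examples).
* **SineSqr fitting.** Levenberg–Marquardt (`minpack.lm::nlsLM`) from 10
  seeded starts (base start: amplitude = data range, centre at the
  maximum, width twice the abscissa span, offset at the minimum).
  Parameters are bounded to the data scale — width in
  \([10^{-3}, 4]\times\) span, amplitude within \(10\times\) the ordinate
  range — because an unbounded width lets the model degenerate into a
  locally-quadratic ramp with runaway amplitude on short noisy spans. A
  negative fitted amplitude is folded into a half-period phase shift so
  the reported \(A \ge 0\). A constant ordinate returns \(A = 0\) with a
  degeneracy flag instead of an error.
* **Grouping algorithm.** A pure gap split cannot separate overlapping
  m/z clouds (e.g. clouds 0.42 Th apart with spreads 0.10/0.15 leave no
  empty 0.2 Th gap at realistic scan counts), and t-test merging can only
  merge, never split. Each gap-delimited chunk is therefore refined by 1-D
  Gaussian-mixture model selection (EM, BIC over equal- and
  unequal-variance models via `mclust`) before the Welch-t merge. Welch's
  unequal-variance test is used because the m/z spreads of neighbouring
  species genuinely differ; no multiple-testing correction is applied to
  the pairwise merge decisions (raw pairwise verdicts are reported).
  Groups smaller than 3 are absorbed into the nearest-mean group so every
  reported group supports a normality test.
* **Ties in window extraction.** Equal intensities resolve by proximity
  to the window centre, then by lower m/z — deterministic extraction.
* **\(D_{QC}\) units.** The activation enthalpy defaults to hartree with
  \(R = 3.1668116\times10^{-6}\) hartree·K⁻¹ (kJ/mol selectable,
  \(R = 8.3144626\times10^{-3}\)); wavenumber lists are used as given, the
  ground state carrying exactly one more mode than the transition state,
  so one uncancelled cm⁻¹ factor remains in \(D_{QC}\) and no unit is
  attached to its output. Imaginary modes must be removed by the caller;
  non-positive entries are rejected, never silently dropped.
* **Fragment at m/z 110.** The protonated-analyte N–C cleavage fragment
  is shipped as protonated 4-aminophenol (C6H8NO⁺, nominal 110),
  consistent with a 42 Da ketene loss; a label of the form
  "[M−CH3CHC=O]⁺" would imply a 56 Da loss inconsistent with the printed
  m/z, so the 110-consistent composition is used.

## The synthetic generator

`simulate_srm()` emulates the statistical structure the method assumes:
per scan, each species emits one centroid with
m/z \(\sim N(\mu, \sigma_{mz})\) and Gaussian (clamped at 0 counts) or
Poisson intensity. `calibration_scenario()` builds a dilution series in
which the per-scan intensity variance follows a log-linear law
\(\ln \mathrm{var} = a + b\,c\) — chosen so that \(\ln D''_{SD}\) is
linear in concentration *by construction*, matching the calibration
transform — with optional lognormal run-to-run noise on each level's
variance and on its mean intensity. A power law is selectable.

Generator defaults and the sizes used by the shipped studies:

* concentration grid 2, 6, 10, 20, 40, 80 ng/mL; scan interval 0.01 min;
  100 scans per level by default;
* variance-law slope \(b = 0.08\) per ng/mL and intercept \(a = 9\),
  spanning roughly 2.7 decades of variance over the grid — a dynamic range
  at which the 5 % run-to-run variance noise, not the finite-sample error
  of the variance estimator, limits the calibration;
* the calibration study in the acceptance tests uses 2000 scans per level
  (a 20 min segment at 0.01 min per scan). At \(n\) scans the sampling
  error of \(\ln \widehat{\mathrm{var}}\) is \(\approx\sqrt{2/n}\)
  (3.2 % at \(n = 2000\)), below the 5 % level noise by design;
* the m/z spread defaults to 0.02 Th so the standard ±0.1 Th window
  captures essentially every centroid (5 standard deviations); a wider
  spread combined with the `"zero"` policy would inject spurious zeros
  whose variance contribution scales with the squared mean intensity.

What the generator does *not* emulate: chromatographic peak shapes, ion
suppression, detector saturation, correlated scan-to-scan drift, isotope
envelopes within one species, and mass-calibration drift. Passing tests on
synthetic data therefore demonstrate the estimators' statistical
behaviour under the stated noise model, not instrument-level validity on
real acquisitions.

## Numerical choices

* The population variance is clamped at zero against rounding; it agrees
  with a two-pass oracle to 1e-12 relative in the property tests.
* \(D_{QC}\) is evaluated wholly in log space,
  \(\exp(\sum\ln\nu^0 - \sum\ln\nu^s - \Delta H^\ddagger/(RT))\): the raw
  frequency products overflow double precision near 200 modes, while the
  log form handles hundreds of modes exactly (verified against the direct
  product on small models).
* Isotope patterns convolve per-element distributions one atom at a time,
  merging peaks into 0.01 Da bins by abundance-weighted mean mass and
  pruning below 1e-14 during accumulation; electron mass is subtracted per
  positive charge in monoisotopic/charged modes only — nominal masses stay
  integer.
* Exhaustive structure search caps the candidate product space (default
  1e6) and keeps the first-enumerated combination on ties, so results are
  deterministic.
* All simulation entry points take an explicit seed and restore the
  caller's RNG stream afterwards.

## Limitations

* The diffusion-parameter scale is taken verbatim; absolute values are
  comparable within a study, not across instruments.
* \(D'\) requires ≥ 4 scans per span and is sensitive to the SineSqr
  fit's identifiability on short spans; prefer \(D''\) for quantification
  and use \(D'\) diagnostically.
* The grouping verdict depends on mixture model selection; with fewer
  than ~6 points per species, BIC cannot resolve overlapping clouds.
* The area comparator implements Savitzky–Golay smoothing, endpoint
  baseline subtraction and trapezoidal integration only; proprietary
  vendor peak detection is out of scope.
* Vibrational inputs for \(D_{QC}\) come from the user's quantum-chemistry
  stack; the package performs no electronic-structure computation.
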