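---
title: "Methods: immobility-defined sleep, circadian periodograms and quartet variant filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immobility-defined sleep, circadian periodograms and quartet variant filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actisleep)
```

`actisleep` implements a complete behavioural-phenotyping analysis chain for
passive-infrared (PIR) actigraphy, together with the family-genetics and
receptor-pharmacology statistics that typically accompany such a study.
This vignette is the package's own account of the methods: the models and
rules, their assumptions, the tunable parameters, the numerical choices, and
the limits of what the synthetic-data tests can show.

## Immobility-defined sleep

PIR sensors poll for movement at high frequency and report percent time
active per 10-s bin. Behavioural sleep is scored from sustained immobility:
if no movement is detected for 4 consecutive bins (40 s), sleep is recorded.
This threshold has been validated against EEG-defined sleep in mice.

The rule's wording leaves one genuine ambiguity: whether the first three
bins of a qualifying immobile run count as sleep. `score_sleep()` therefore
exposes both conventions as first-class options rather than guessing:

* `onset = "fourth_bin"` (default, the literal rule): a maximal immobile run
  of R ≥ 4 bins contributes R − 3 sleep bins, starting at the fourth;
* `onset = "run_start"`: the whole run is scored, as much of the 40-s
  immobility literature does.

The two differ by exactly 30 s per sleep bout, which the test suite asserts.
"Immobile" means percent-active at or below a configurable `epsilon`
(default 0: any detected movement breaks a run). Runs truncated by the trace
edges are scored from observed bins only.

## Bouts and their categories

A bout of activity is a maximal run of consecutive active bins; its
intensity is the mean per-bin percent-active over the bout (six consecutive
bins with the sensor active 30 s in total: a 1-min bout at 50% intensity).
Sleep bouts are maximal runs of sleep-flagged bins.

Bout lengths are categorised into the four canonical classes — <1 min,
1–10 min, 10 min–1 h, >1 h — as half-open intervals [0, 60), [60, 600),
[600, 3600), [3600, ∞) seconds. Edge ownership is not fixed by convention in
the field, so the half-open reading (a 60-s bout belongs to 1–10 min) is a
package decision, applied consistently and asserted in tests. Counts are
reported both as raw totals and per day observed; intensity categories
default to deciles and are configurable.

## Chi-square periodogram and tau

Rhythmicity is quantified with the Sokolove–Bushell chi-square periodogram.
For a candidate period of $P$ analysis bins over a series of $N$ bins with
column means $\bar x_h$ (over $n_h$ entries) and grand mean $\bar x$:

$$Q_p \;=\; \frac{N \sum_{h=1}^{P} n_h\,(\bar x_h - \bar x)^2}
                 {\sum_{i=1}^{N} (x_i - \bar x)^2}$$

Under a white-noise null $Q_p \sim \chi^2_{P-1}$ approximately, and the
per-period significance line is the $\chi^2$ quantile at $1-\alpha$
(default $\alpha = 0.01$). Incomplete final cycles are used as-is (column
means over unequal counts); a truncate-to-complete-cycles mode is available.
No correction is applied across candidate periods, matching the single
plotted significance line of conventional actigraphy software. A constant
series has $Q_p \equiv 0$ by definition.

Numerical notes:

* The $\chi^2$ approximation is exact only as $N/P$ grows: the denominator
  contains the between-column sum of squares, so for short series with long
  candidate periods the statistic runs conservative (measured ≈0.7%
  exceedance at the 1% line for $N = 480$, $P \le 49$; ≈0.9–1.1% for
  $N = 2000$, $P \le 60$). Calibration tests therefore use long series.
* Any integer multiple of a true period also folds perfectly, so the
  periodogram scores multiples as high as the fundamental. Search ranges
  should be chosen below the first multiple — as the defaults are:
  20–28 h for mouse actigraphy, 16–120 h for ultra-long human diaries.
* `estimate_tau()` returns the period of maximum $Q_p$ within the search
  range only when it exceeds its significance line, with ties broken toward
  the shorter period (deterministic); otherwise the series is called
  arrhythmic (`NA`).
* Mouse traces are down-binned to 6-min analysis bins before the
  periodogram (0.1-h period resolution at hourly-scale periods); diaries
  are analysed at their native 1-h resolution. Both are configurable.

Per-block summaries come from `light_response_table()`: each lighting block
of at least 9 uninterrupted days (the analysis-grade threshold) yields a tau
estimate and a tau-adjusted daily activity, $(24/\tau) \times$ mean daily
activity, which corrects per-24-h averages for the drifting subjective day.
Double-plotted actograms (`double_plot_actogram()`) lay each day beside the
next so a non-24-h rhythm drifts as a diagonal; folding at the true tau
minimises column variance, which the tests check numerically.

## The synthetic cohort generator

No public PIR dataset accompanies this pipeline, so the generator is a
first-class module that creates cohorts with the statistical structure the
analyses assume: a two-state alternating-renewal process (active/immobile)
whose run lengths come from a four-class mixture matching the bout
categories, log-normal within each class and truncated to the class
interval. Because circadian phase and genotype act only on the class
*weights*, class-conditional length distributions stay fixed — planted
effects on category counts are clean by construction.

Key parameters (defaults in parentheses):

* `intrinsic_tau_h` (23.8 h) and `aschoff_slope` (0.4 h per log10(lux+1)):
  the internal period in darkness and its Aschoff-rule-like lengthening with
  constant light, $\tau(\text{lux}) = \tau_0 + s \cdot \log_{10}(\text{lux}+1)$.
  A linear log-lux law is the simplest form consistent with "tau lengthens
  with brighter constant light"; it is a generator convention, not an
  estimate.
* `nocturnality` (6): the strength of the day/night tilt on class weights.
  During subjective night, activity-run weights shift toward longer classes
  and immobility-run weights toward shorter ones, and conversely by day. A
  value of 6 reproduces the strong dark-phase dominance of C57BL/6 PIR
  records; the realised dark:light activity ratio grows monotonically with
  the parameter.
* Clock gating: state runs are truncated at subjective day/night
  transitions. Without gating, long immobile runs straddle the transition
  and blur activity onset; with it, onsets are sharp, as in real actograms,
  and the periodogram recovers planted taus to within one 0.1-h step.
* `brief_bout_deficit` (1 = none): multiplies the sub-minute class weight
  for both activity and immobility runs in the tagged genotype; 0.6 models a
  40% deficit in brief bouts of activity and of sleep.
* In LD blocks the phase is entrained to the light cycle (subjective night =
  scotophase); in DD/LL it free-runs at $\tau(\text{lux})$, continuous
  across block boundaries.
* Seeding is hierarchical: one global seed deterministically yields
  per-subject streams, so cohorts are reproducible subject-wise.

The bout-length mixture defaults (class weights ≈ 0.55/0.30/0.13/0.02 for
activity, 0.45/0.33/0.19/0.03 for immobility; log-normal medians near the
geometric mid of each class) are calibration-free placeholders: no
quantitative bout-length distribution exists to fit them to. They produce
roughly a hundred bouts of each kind per day, in the range reported for
singly-housed mice.

What the generator does *not* model: EEG vigilance states, the two-process
(homeostat + oscillator) interaction, masking (direct suppression of
activity by light, distinct from period lengthening), ultradian physiology
beyond bout statistics, or sensor artefacts. Passing tests therefore show
that the analysis chain recovers what this renewal model plants — not that
it captures every feature of real mouse behaviour.

The diary generator alternates wake and sleep episodes of mean length
`cycle_length_h × (1 − sleep_fraction)` and `cycle_length_h ×
sleep_fraction`, each jittered log-normally (σ = 0.08 on the log scale,
keeping the realised duty cycle within a few percent of target), emulating
an ultra-long (e.g. 72-h) sleep-wake cycle recorded hourly over 27–28 days.

## Group statistics

`two_way_rm_anova()` is the classical univariate mixed design: genotype
(between subjects) is tested against subject-within-genotype; the
within-subject factor and the interaction against the subject × level
residual. No sphericity correction is applied and equal variance is
assumed, matching standard practice for these designs in behavioural work.
Percent variation explained is $100 \cdot SS_{\text{effect}}/SS_{\text{total}}$
with $SS_{\text{total}}$ summed over all strata, so the column totals 100.
Post-hoc genotype comparisons are pooled-variance t tests at each
within-subject level, Bonferroni-multiplied by the number of levels and
capped at 1. The SS decomposition is verified in tests against a
brute-force mean-decomposition oracle, exactly to floating tolerance.

`welch_t_test()` and `log_geomean_t_test()` wrap the standard two-sample
procedures (Welch–Satterthwaite df; pooled t on logs with geometric means
reported — scaling both groups by a constant leaves the log-scale statistic
unchanged). Degenerate zero-variance inputs return P = 1 when means agree.

`compare_distributions_skewnormal()` compares two event-amplitude samples
(e.g. mEPSC amplitudes, pre-filtered by the 2-ms rise-time rule) by binning
each into a 21-bin relative-frequency histogram on a shared range, fitting
a three-parameter skew-normal curve
$f(x) = \tfrac{2}{\omega}\,\phi(z)\,\Phi(\alpha z)$, $z = (x-\xi)/\omega$,
by least squares pooled and per group, and forming the
extra-sum-of-squares F statistic with df (3, 2·bins − 6) — (3, 36) at the
default bin count. The numerator df of 3 reflects the three shared
parameters released; a possible fourth (amplitude) parameter is
deliberately not used, since the df convention above is the one consistent
with reported values in this literature. Two caveats are documented rather
than hidden: histogram bin errors are correlated multinomial quantities,
so the F test is mildly anti-conservative (≈15% rejection at α = 0.05 on
true nulls in our simulations) — it is retained because it is the field's
convention — and fits use Nelder-Mead restarts from moment-based starting
points with non-convergence reported, not silently dropped.

## Variant filtering for a family quartet

The filter chain reproduces a standard rare-disease prioritisation for a
father–mother–two-affected-sons family:

1. **Consequence**: keep protein-altering classes (nonsynonymous SNV, stop
   gain/loss, frameshift/inframe indel, splice site).
2. **Frequency**: exclude variants with population allele frequency
   strictly greater than 0.005 in any reference panel (absent annotation =
   novel = 0; exactly 0.005 is retained), any internal-cohort
   homozygote/hemizygote, more than five internal-cohort heterozygotes, or
   any gnomAD hom/hemi observation.
3. **Inheritance**: simple recessive (sons 1/1, parents 0/1), compound
   heterozygous (≥2 passing variants in one gene, each het in both sons and
   in exactly one parent, with both parents represented), X-linked
   recessive (chrX; sons hemizygous-alt, mother het, father
   hemizygous-ref), and shared de novo (sons het, parents 0/0, confident
   calls in all four members).

The genotype log-likelihood ratio convention: PL fields are normalised so
the called genotype has PL 0; the ratio is −(second-smallest PL)/10, i.e.
the log10 likelihood of the best alternative genotype relative to the call.
It is ≤ 0 by construction and more negative means more confident; the de
novo model requires it below −5 in every member. Records without PL are
ineligible for the de novo model but are not errors.

Multi-allelic sites are split into one biallelic record per alternate
allele before filtering (so frequency rules apply per allele); alleles
other than the focal alternate are recoded as reference, and PL vectors are
subset to the matching sub-genotypes. Each filter stage is a pure subset
operation, so stage order cannot change the final candidate set — a
property the tests verify on random inputs, along with funnel additivity
(input = output + removed, per stage).

## Dose-response fitting

`fit_dose_response()` fits the three-parameter log-logistic curve with Hill
slope fixed at 1,
$Y = \text{bottom} + (\text{top}-\text{bottom}) / (1 + 10^{\log_{10}EC_{50} - X})$
with $X = \log_{10}[\text{agonist}]$, by Levenberg-Marquardt least squares.
"Three-parameter" is read as free bottom/top/EC50; a fixed-bottom = 0
variant is available by flag since published fits do not always state the
constraint. The optimiser restarts from three deterministic initial EC50
guesses (geometric mean, minimum and maximum of the tested concentrations)
and keeps the best fit — reproducible without a seed, robust to local
minima. On noiseless model-generated data the EC50 is recovered to
relative 1e-6 and the residual SS is zero to tolerance; with 5% noise at 8
concentrations the recovery bias is ~3%, comfortably under 10%.
Responses are expressed relative to a near-saturating reference application
(`normalize_responses()`), and agonist efficacy is summarised by the
kainate/glutamate peak ratio in percent (`ka_glu_ratio()`).

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic data
at deliberately modest sizes, chosen to exercise every code path with
comfortable statistical margins: 6 + 6 subjects × 7 LD days for the
bout-deficit power study (100 effect + 100 null replicate cohorts in the
test suite; 40 + 40 in the reporting script), 10-day lighting blocks for
tau work, 20 DD traces for period recovery, ~12,000 period evaluations for
the significance-line calibration, 500 background variants around each
planted candidate, and 200 replicate noisy dose-response fits. All
quantities are recomputed from scratch at run time from a single
command-line seed.

## Known limitations

* Behavioural sleep is a proxy; no vigilance-state (REM/NREM) information
  exists in PIR data, and none is claimed.
* The generator's bout-length mixture is a structural placeholder, not a
  fitted model; absolute bout counts should not be read as predictions.
* Masking is not modelled, so light-condition analyses here exercise period
  lengthening only.
* The histogram-based F test inherits the anti-conservatism noted above;
  for confirmatory use, a bootstrap of the fitted comparison would be the
  conservative alternative.
* The internal-cohort filter consumes per-record count annotations
  (`CHET`/`CHH`); the cohort itself is not modelled.
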