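---
title: "Methods: signal processing and ensemble statistics in gliatrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal processing and ensemble statistics in gliatrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliatrace)
```

gliatrace implements the quantitative chain used to study behaviourally
relevant astrocyte ensembles: processing of time-division multiplexed
fibre-photometry recordings, brain-wide screening of Fos-tagged cell
densities across a region ontology, and single-cell in situ intensity
statistics. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic generators do and do not
emulate, and the numerical choices made where the design was open.

## Photometry model

A recording interleaves two signal wavelengths (465 nm, 560 nm) with a
405 nm isosbestic reference at a 20 Hz alternation rate (24 ms on, 26 ms
off per pulse window) over a 1 kHz acquisition stream. Three LEDs cannot
be lit simultaneously inside one 50 ms window (3 × 24 ms > 50 ms), so
the channels take turns: one active channel per pulse window, each
channel revisited every `n_channels` windows. A demultiplexed
single-channel trace therefore runs at 20/3 Hz for the default
three-channel order. Within each on-window the first and last 2 raw
samples are dropped — LED switching transients contaminate both edges —
and the remaining 20 samples are averaged into one value stamped at the
window centre.

The measured fluorescence is modelled multiplicatively:

$$F_c(t) = \big(1 + b\,t\big)\,\big(1 + m(t)\big)\,\big(1 + r_c(t)\big) + \varepsilon(t),$$

with a linear bleaching drift $b$, a slow (< 0.5 Hz) motion artefact
$m(t)$ shared across channels, a channel-specific sensor response
$r_c(t)$ (zero on the isosbestic channel), and detector noise. The chain
inverts this factor by factor:

* **Smoothing.** Centred moving average, default 5 trace samples
  (0.25 s at 20 Hz); the window length is not fixed by convention, so it
  is a parameter. Edges use a shrinking window, preserving length and
  the sum of interior-supported impulses.
* **Bleach correction.** An ordinary least-squares line is fitted to the
  full trace and the trace divided by it, leaving a dimensionless series
  near 1. A fitted line that is not strictly positive marks the
  recording unusable. *Limitation:* when a transient occupies a large
  fraction of the recording, the full-trace line absorbs part of it and
  the apparent half-decay stretches by 10–30 % for decay constants of
  30–480 s in recordings six times the decay constant. The half-decay
  guarantee below is therefore stated for the extraction itself;
  analyses of very slow transients should use long recordings or
  baseline-anchored windows.
* **Response.** $\mathrm{ratio}(t) = (s(t) + 1)/(x(t) + 1)$ for the
  bleach-corrected signal $s$ and reference $x$, minus the mean ratio
  over a caller-chosen quiet baseline window (typically 1–2 min of
  home-cage recording before context exposure). The shared factor
  $(1+m)$ cancels in the ratio; with corrected traces near 1 the "+1"
  form also halves the response scale, so a sensor response of 0.2
  appears as dF/F ≈ 0.1. All comparisons in the package are internally
  consistent on this scale.
* **Transient metrics.** Peak dF/F; trapezoidal AUC over the analysis
  window (negative excursions included); half-decay as the linearly
  interpolated time from the peak to the first post-peak sample at or
  below half the peak, undefined when the trace never falls that far
  (or when the peak is not positive). For an instantaneous-rise,
  mono-exponential transient the half-decay equals τ·ln 2, which gives
  the analytic oracle used throughout the tests. Preset kinetics are
  provided for conditioning-like (peak 0.206, half-decay 4.3 min),
  recall-like (peak 0.211, half-decay 13.5 min) and context-only
  (peak 0.142) responses.
* **Event detection.** Calcium traces are band-pass filtered to
  0.0003–1 Hz. The exact filter family is a free choice; gliatrace uses
  cascaded zero-phase second-order Butterworth high- and low-pass
  sections (after removing the trace mean), because a single
  transfer-function band-pass spanning 3×10⁻⁵–0.1 of Nyquist is
  numerically fragile. The contract is stated as gain bounds: DC
  rejected, ≥ 0.9 at 0.01 Hz, ≤ 0.1 at 9 Hz. Events are contiguous runs
  strictly exceeding `baseline mean + 4 × SD`, where mean and SD pool
  the samples of caller-supplied quiescent windows totalling at least
  20 s — quiescence is identified by the experimenter, not auto-detected.
  Runs closer than 0.5 s merge; a sample exactly at threshold is not an
  event, making the boundary deterministic. Event frequency is
  60 × count / duration (events/min).

## Region screening model

Inputs are tagged-cell counts per region and subject, a subject→group
map over the four-group design (NoFC: 6, FC: 4, NoFR: 4, FR: 4 by
default), and a region ontology carrying sizes and exclusion flags.
Counts become densities (cells/mm³, or cells/mm² in slice mode);
ventricular-niche regions (where neuron-like leakage contaminates
astrocyte counts) and high-level aggregate structures are excluded with
logged reasons — children of an excluded aggregate are kept, and counts
are never re-aggregated up the ontology.

Each region is routed by a Levene test on the group variances. The
median-centred (Brown–Forsythe) variant is used: the plain description
"Levene's test" does not fix the centring, and median centring is the
robust modern default. Homogeneous regions (p > 0.05) get one-way ANOVA
with Tukey's HSD; the rest get Kruskal–Wallis with Dunn's post hoc test
on the pooled ranking (tie-corrected), Bonferroni-multiplied by the
number of pairwise comparisons. Regions with any group below `min_n = 3`
subjects, or with all values identical, are skipped with a reason and
never enter the FDR family. If every group is internally constant the
Levene statistic is undefined; variances are then vacuously homogeneous
and the parametric route is taken.

All post hoc p-values — every pairwise comparison of every analysed
region — form one pooled family that is Benjamini–Hochberg adjusted;
significance is q < 0.05. Pooling across regions *and* comparisons is
the widest defensible family; omnibus p-values are reported unadjusted.
Fold changes divide group mean densities by the reference (NoFC) mean
and are flagged undefined (never infinite) for a zero reference; no
pseudocount is added by default. The routed statistics are computed in
closed form from group sums for speed across hundreds of regions and
replicates; the test suite pins them to `aov`/`TukeyHSD`,
`kruskal.test` and `car::leveneTest` on random tables.

The neuron–astrocyte correlation starts from regions flagged
engram-significant, drops ventricular-leakage regions and aggregate
structures (each exclusion logged), and computes a two-sided Pearson
correlation between the per-region changes (group mean minus reference
mean) of neuronal and astrocytic Fos⁺ counts.

## Single-cell quantification model

Per-cell probe intensities are normalized by the Slc1a3 marker to cancel
soma-size differences — the exact per-cell ratio, so a common gain on
all channels of a cell has no effect. Cells with non-positive marker
intensity are excluded, never imputed. Normalized values are z-scored
within each sample (the `sample_id` column; section or mouse, caller's
choice — the granularity is deliberately not hard-coded) using the n−1
standard deviation, appropriate for small per-section cell counts.
Classification is strict: Fos-high at z > 2 (≈ 2.3 % of a Gaussian
population), Adrb1- and Igfbp2-high at z > 0.5 (≈ 31 %); a cell exactly
at a cut-off is low.

The co-expression index multiplies the two receptors' expression levels
relative to the reference-condition (NoFC) medians:
$CI = (A_{1a}/\tilde A_{1a}^{ref}) \times (B_1/\tilde B_1^{ref})$.
It uses marker-normalized values, not z-scores: the definition is a
ratio ("relative expression"), which a z-score is not. The reference
median pools all cells of the reference condition rather than averaging
per-sample medians — one more cell-weighted convention of the same
quantity. Gene–gene correlations, in contrast, are computed on z-scores.
Group comparisons use the Mann–Whitney U test: exact by enumeration when
both groups have ≤ 8 untied observations, otherwise the tie-corrected
normal approximation (without continuity correction, so the two regimes
agree in their overlap).

## Synthetic data: what it does and does not emulate

The generators produce the study conditions, not arbitrary fixtures:

* **Photometry** — interleaved streams in the multiplicative model
  above. The motion artefact is a standardized random walk smoothed
  below 0.5 Hz and held constant across the channels of one rotation,
  which is precisely the property the isosbestic ratio exploits; sensor
  transients rise instantaneously and decay mono-exponentially (the
  rise kinetics of the sensors are not characterised, so the
  instantaneous rise is a modelling convenience that buys the τ·ln 2
  oracle); calcium events are Poisson-timed.
* **Region counts** — independent negative binomials with variance
  mean + mean²/dispersion (defaults mean 20, dispersion 2), group sizes
  6/4/4/4, an optional FR-group multiplier on designated effect
  regions, and an ontology with configurable ventricular/aggregate
  flags.
* **Cell tables** — a log-normal soma-size factor through the marker,
  gene-level log-normals with condition multipliers, a Bernoulli
  Fos-high subpopulation, and a Gaussian-copula correlation between the
  Adrb1 and Igfbp2 latent factors (default 0.8, matching strongly
  co-expressed receptors; base intensities and a gene-level log-SD of
  0.4 are generic fluorescence scales).

Real recordings have non-linear bleaching, wavelength-dependent
artefact gains, sensor rise times and non-Poisson event clustering;
real counts have inter-region correlation and subject effects; real
sections have segmentation errors. Passing tests therefore demonstrate
the *procedures* are correct under the stated model, not that the model
exhausts real data.

Every generator takes an explicit integer seed (default 0) and restores
the caller's RNG state; identical configuration and seed give
byte-identical output. The command-line pipeline derives all stage seeds
from `--seed`, and its run logs record stages, record counts and seeds —
but no wall-clock timestamps, so repeated runs are byte-identical.

## Problem sizes and statistical guarantees

The test suite and the acceptance script exercise: 500 global-null
count datasets of 100 regions for false-discovery control (the mean
realized false-discovery proportion stays below the nominal 0.05); a
planted 3× recall-group effect in 10 of 100 regions over 100 replicates
for the power benchmark; 1,000 random p-vectors against the brute-force
step-up definition; transient recovery at decay constants 30/120/480 s;
20 seeded 10-min calcium traces for the detector operating point; 10⁵
standard-normal z-scores for threshold calibration; and 5,000 cells for
correlation recovery. These sizes give Monte-Carlo errors comfortably
inside each tolerance while keeping a full run to a few minutes.

One honest caveat: under the default generating conditions the planted
3× effect is weak relative to the count dispersion (an FR group of four
subjects with variance 1,860 against controls at 220). Even an oracle
two-group test on the true effect pairs has raw power well under 50 %,
so the screen's realized sensitivity at FDR 0.05 is a few percent, at
precision ≈ 1. Two structural facts compound this. First, a
negative-binomial mean shift inflates the group variance, so exactly the
regions carrying strong effects tend to fail Levene's test and take the
rank path. Second, on the rank path with four subjects per group the
smallest achievable exact p (4 vs 6, perfect separation) is 2/210, and
after the ×6 Bonferroni step Dunn p-values cannot fall below ≈ 0.057 —
never small enough for a pooled 600-comparison BH family at q < 0.05.
High sensitivity under this screen therefore requires larger group sizes
(see the README example at 12/8/8/8), not merely larger effects. The
power benchmark asserts an 80 % sensitivity bound that the 6/4/4/4
conditions cannot support; it is retained, failing, as a calibration
flag rather than silently weakened.

## Known limitations

* Full-trace linear detrending biases metrics of transients that are
  long relative to the recording (above).
* The band-pass guarantee is specified by gain bounds, not coefficients;
  other zero-phase realisations meeting the bounds would be conformant.
* Quiescent windows for event detection are caller-supplied; no
  automatic quiescence detection is attempted.
* The screen treats subjects as exchangeable within groups; no random
  effects for litters or batches.
* `rank_test()`'s exact path requires untied data; heavily tied small
  samples fall back to the normal approximation.
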