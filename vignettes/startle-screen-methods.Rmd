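---
title: "Methods: acoustic-startle screen analysis and its synthetic-data model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic-startle screen analysis and its synthetic-data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startlescreen)
```

## The assay and its statistics

Larval zebrafish respond to acoustic stimuli with stereotyped C-shaped escape
bends. Responses initiated within ~15 ms of the stimulus are short-latency
C-bends (SLC), driven by the Mauthner-cell circuit; slower responses are
long-latency C-bends (LLC). Three phenomena are quantified, all as functions
of per-stimulus SLC initiation:

* **Baseline initiation** — the fraction of stimuli in a window that evoke an
  SLC (or any movement), reported as a percentage. Low-intensity stimuli are
  calibrated to evoke SLCs on ~25% of presentations, high-intensity on ~75%.
* **Habituation** — the decline of SLC initiation under rapid (short-ISI)
  repeated stimulation:
  \[
  \mathrm{hab} = 100 \times \left(1 -
    \frac{\text{SLC rate, late window}}{\text{SLC rate, first 10 high stimuli}}\right).
  \]
  In the 60-stimulus screen assay the late windows are stimuli 41–50 and
  51–60 (both reported); the first-window denominator is the ten unpaired
  high-intensity stimuli 2, 5, ..., 29. In the 50-stimulus habituation assay
  the windows are 41–50 over 11–20.
* **Prepulse inhibition (PPI)** — suppression of startle to a high-intensity
  pulse preceded 400 ms earlier by a low prepulse:
  \[
  \mathrm{PPI} = 100 \times \left(1 -
    \frac{\text{SLC rate, paired stimuli}}{\text{SLC rate, unpaired high stimuli}}\right).
  \]

Larvae that fail to initiate any movement to **60% or more** of stimuli are
excluded before any statistic is computed (ties at exactly 60% are excluded).
Where the assay literature leaves the order ambiguous, this package applies
exclusion first, then computes every metric on the kept larvae.

Per-larva ratios with a zero denominator (no SLC in the first window) are
**undefined**, not 0 or 100: silently substituting either value would bias
group means, so such larvae are dropped from that metric and the n actually
used is reported per metric by `group_summary()`. Values are not clamped —
facilitation legitimately produces negative habituation or PPI percentages.

## Hit calling

Each compound group's mean readout is standardized against the pooled
distribution of non-treated control group averages:
\[ z = \frac{\bar{x}_\text{treated} - \bar{x}_\text{control}}{s_\text{control}}, \]
with \(s\) the sample SD (denominator \(n-1\)) over control group means
pooled across all experimental days. A compound is a hit when its z-score
passes the one-sided 99% standard-normal quantile, 2.326, in the beneficial
direction; the comparison is inclusive (`z >= 2.326`) because the printed
threshold is itself the rounded quantile. Day-matched z-scoring is possible
in principle but the pooled distribution is what the screen design describes,
so pooled is the implemented default. A Gaussian may be fitted to the control
histogram (`fit_control_gaussian()`) for display; it never feeds the
z-scores.

Target-class enrichment among hits uses a one-sided Fisher's exact test
(upper hypergeometric tail) at a significance level of 0.05, with no
multiple-testing correction across classes by default (a BH option exists)
— this mirrors how screening enrichment tables are conventionally reported.

## Brain-difference mapping

`voxelwise_map()` compares two groups of registered ratio volumes (standing
in for pERK/tERK immunostain stacks) voxel by voxel with the Mann–Whitney U
statistic under its normal approximation: mid-ranks, tie-corrected variance,
no continuity correction, sign positive when the second group is
stochastically larger. Zero-variance voxels get z = 0, p = 1. Significance is
masked by the Benjamini–Hochberg step-up rule over all voxels at
q = 0.00005, the level used in whole-brain activity mapping. The BH
procedure is the package's choice where the upstream mapping software's
exact FDR routine is unspecified; it is implemented from the definition and
cross-checked against `stats::p.adjust` in the tests.

Two ROI summaries are reported. The headline "signal in ROI" is the sum of
|z| over significant voxels of the dominant sign inside the ROI — published
ROI signal magnitudes (hundreds) are consistent with a sum, not a per-voxel
mean, so the literal mean z over significant voxels is reported alongside
under its own name rather than silently conflated. Label enrichment is the
ratio of significant-|z| density inside an anatomical label to the
brain-wide density; values > 1 indicate relative enrichment. No acceptance
criterion depends on the absolute scale of either quantity.

## What the synthetic generator emulates

`simulate_cohort()` draws, for each larva and stimulus, an SLC with a
probability determined by the stimulus type, then an LLC (when no SLC
occurred) with the conditional probability that makes total movement match
the any-movement rate:

| parameter | default | basis |
|---|---|---|
| `p_slc_low`, `p_slc_high` | 0.25, 0.75 | the assay's stated design targets |
| `p_any_low`, `p_any_high` | 0.50, 0.95 | generator choice (realistic any-movement rates) |
| `h_g` (wt / het / hom) | 0.85 / 0.55 / 0.25 | generator choice reproducing the ordering wt > het > double-homozygous |
| `ppi_g` (wt / het / hom) | 0.65 / 0.50 / 0.35 | generator choice, same ordering rationale |
| `tau` | 8 stimuli | places the last ten habituation stimuli near asymptote, so expected habituation ≈ `h_eff` |
| SLC latency | N(8, 2) ms, truncated to (2, 14) | below the fixed 15 ms class boundary |
| LLC latency | N(28, 6) ms, truncated below 16 | above the boundary |
| `nonresponder_fraction` | 0.05 | generator choice; scaled (×0.25) response probabilities put these larvae well under the 40% response level |
| `day_sd` | 0 (off) | optional logit-scale day effect |

Habituation decays the SLC probability multiplicatively over the short-ISI
stimuli; the any-movement rate stays at `p_any`, i.e. suppressed SLCs
reappear as LLCs. This matches the observation that habituation reduces the
short-latency response specifically, and keeps the exclusion rule's
denominator stable. Drug effects are additive shifts on habituation capacity
and/or PPI suppression, scaled linearly in dose relative to a reference dose
and clamped to [0, 1] — a deliberately simple dose model adequate for
planted-effect recovery tests; no pharmacokinetics are modelled.

Genotypes are drawn from the exact Punnett expectation of the screening
cross (`+/-;-/-` × `-/-;+/-`, four mutant classes at 25% each); pooled SLC
design rates are applied to all genotype classes because per-genotype
baseline rates are not separately specified anywhere.

**What a green test does and does not establish.** The generator produces
exchangeable larvae with independent Bernoulli responses given their class;
real screens have within-day correlation, plate effects, drifting baselines
and kinematic correlation structure that are not modelled (a day effect on
the logit scale can be switched on, but defaults to off). Recovery tests
therefore establish that the analysis code implements its formulas and
thresholds correctly and has the nominal operating characteristics under the
stated model — not that the screen would achieve those characteristics on
real behavioral data.

## Numerical and design choices

* **15 ms SLC/LLC boundary** — classification is delegated to tracking
  software in the real assay and no threshold is printed; the fixed cutoff is
  a package convention, and simulated latency distributions are truncated so
  the boundary is never ambiguous.
* **Inclusive hit threshold** (`z >= 2.326`), see above.
* **Fisher's test one-sided** in the enrichment direction: the screening
  question is enrichment. A two-by-two helper (`fisher_exact_2x2()`) exposes
  the exact upper-tail sum directly.
* **Paired-stimulus representation** — a paired low+high presentation is one
  stimulus index (the schedule's 60-event count and the printed index lists
  require this); the event stores the prepulse onset and the scored high
  pulse 400 ms later.
* **Degenerate inputs** — zero-variance controls refuse to z-score (error,
  not Inf); zero-variance voxels give z = 0; empty ROIs and overlapping
  metric windows are errors; undefined ratios are `NA` and logged out of the
  averaging n.
* **Determinism** — every stochastic entry point takes an explicit seed;
  per-day streams in `simulate_screen()` are derived from the master seed;
  the pipeline manifest carries no timestamp so identical (config, seed)
  runs are byte-identical.
* **Volumes as text** — 3D stacks interchange as long-format CSV
  (fish, group, x, y, z, value) rather than TIFF, since the analysis is
  format-agnostic once volumes are arrays in memory.

## Scaling of the test suites

The end-to-end recovery suite runs a 30-day × 14-compound screen (420
compounds, 8 planted strong habituation restorers, groups of 32) instead of
the full 60-day, 1134-compound design, purely for runtime; planted effects
are ≥ 3 control SDs by construction and verified in-test before recall is
asserted. The null-map property (no voxels rejected at q = 5e-5 on 16,000
null voxels) is checked over 15 replicates.

## Known limitations

* The simulator's independence assumptions understate real between-larva and
  between-day variance; absolute control SDs from simulation should not be
  read as estimates of empirical screen variance.
* Published screen hit counts and enrichment p-values depend on unpublished
  raw behavioral data and library class sizes; they are procedures this
  package can execute, not numbers it can reproduce.
* The "signal in ROI" convention approximates a published summary whose
  exact definition is not derivable; both candidate readings are reported.
* ANOVA-family group comparisons, image registration, kinematic tracking and
  RNA-seq processing are out of scope; standard tools cover them.
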