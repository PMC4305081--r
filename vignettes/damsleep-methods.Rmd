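---
title: "damsleep: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{damsleep: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damsleep)
```

This vignette is the package's own account of the science it implements:
the scoring and comparison conventions, the statistical machinery, what
the synthetic-data generators emulate (and what they deliberately do not),
and the choices made where the design was genuinely open.

## Sleep from beam-break actigraphy

Drosophila Activity Monitors report, per fly, the number of infrared-beam
crossings in 1-minute bins. The field's operational definition of sleep —
adopted unchanged here — is a maximal run of at least five consecutive
minutes with zero counts; each such run is one sleep episode.
`score_sleep()` implements exactly this rule.

Three boundary conventions needed fixing where the definition is silent:

* **Edges.** Runs touching the start or end of the recording count as
  episodes if long enough. This follows the definition literally; a
  `censor_edges` flag drops them for users who prefer censoring, since an
  edge run's true duration is unknown.
* **Missing minutes** (monitor dropouts, masked gaps, invalid status
  codes) break inactivity runs and are scored neither sleep nor wake. The
  alternative — bridging a gap — could fabricate sleep from absent data,
  so the conservative behaviour is the default and the only one offered.
  For the same reason the DAM parser never zero-fills gaps: the gap
  policy is `error` by default and `mask` on request.
* **Window attribution.** A 12-hr light/dark window that cuts an episode
  receives only the in-window *minutes* (so minutes are conserved:
  sleep + wake + missing = window length, always), while the episode's
  *count and duration* go to the window containing its first minute. This
  keeps totals exactly additive across windows and episode statistics
  unambiguous.

`period_architecture()` computes the standard per-window metrics (total
sleep, episode count, mean and maximum episode duration, activity while
awake), `sleep_profile_binned()` the ZT0-aligned binned profile (bins must
divide 1440, default 30 min), and `average_across_days()` the per-fly
arithmetic mean across days — three complete days in the standard assay —
with missing values excluded pairwise and partial windows dropped by
default.

*Activity while awake* is total counts divided by waking minutes. It is a
slightly biased estimator of the underlying waking activity rate, because
waking minutes that happen to have zero counts can be absorbed into scored
sleep; at realistic rates (≈3 counts/min) the bias is below ~2 % and the
metric serves its purpose — distinguishing sleep changes from locomotor
impairment — unchanged.

## The temperature-shift design

Thermogenetic effectors are switched by moving flies from their rearing
temperature (18 or 22 °C) to 31 °C, but heat itself alters sleep in a
genotype-dependent way. The analysis therefore subtracts, per fly, the
baseline-day value of a window from the same fly's value in the matching
shift (or recovery) window, and only then compares genotypes:

* estimate = mean(experimental deltas) − mean(control deltas), reported as
  minutes gained or lost;
* two comparisons, one per genetic control (GAL4/+ and UAS/+), each with a
  two-sided Mann–Whitney test on the per-fly deltas;
* the **conservative p** — the numerically greater of the two — is the
  reported one, so an effect is only claimed when it holds against both
  controls.

Open points resolved as package defaults: the Mann–Whitney runs on the
per-fly deltas (consistent with the baseline-subtraction pipeline; a raw
mode exists for constitutive designs, where day-averaged raw metrics feed
the same machinery); the baseline is the single pre-shift day of the same
light type (configurable, and `paired_day_deltas()` supports repeated
shift designs where day 1 baselines day 2 and day 3 baselines day 4);
error bars on a difference of group means combine the two SEMs in
quadrature, a documented choice since mean ± SEM plots of group
differences do not define propagation.

## Rank statistics

The tests are implemented in the package so small-sample behaviour is
exactly specified:

* `mann_whitney_u()` — midranks; exact two-sided p
  (`min(1, 2·min(P(U≤u), P(U≥u)))`) from the full null distribution of U,
  built by a lattice-path dynamic program, whenever `min(n, m) ≤ 8` and
  there are no ties; otherwise a tie-corrected normal approximation with
  continuity correction. Identical samples give p = 1 by convention. The
  threshold 8 keeps exhaustive enumeration cheap while covering the group
  sizes typical of imaging experiments.
* `kruskal_wallis()` — tie-corrected H against χ²(k−1). With two groups H
  equals the square of the uncorrected Mann–Whitney z, so the two p values
  agree exactly without the continuity correction and differ by at most
  the correction's effect (≈0.02–0.03 at n = m = 12) with it.
* The imaging convention is a gate: pairwise Mann–Whitney tests of the
  experimental group against each negative control run only when the
  Kruskal–Wallis p < α. The gate level is implied rather than stated in
  common usage; it defaults to 0.05 and is configurable.

A type-I-error check is part of the acceptance suite: under the null
(n = m = 12, 2000 replicates) the rejection rate at α = 0.05 sits in
[0.03, 0.07] — slightly conservative, as expected with the continuity
correction.

## Fluorescence traces

Recordings are 2 Hz ROI-mean traces with 30 s of pre-stimulus baseline.
For single-channel sensors, ΔF/F = (Fₙ − F₀)/F₀ × 100 % with F₀ the first
frame (a pre-stimulus-mean option exists); the series is exactly zero at
frame 1 and invariant to any positive gain. The response is the extremum
over the whole recording — maximum for GCaMP/SpH-type sensors, minimum for
Arclight, whose fluorescence decreases on depolarization. Restricting the
search to a window is an option, but the default searches the full
recording because the convention does not exclude the baseline.

For FRET sensors both channels are recorded; the per-frame ratio is
normalized to the first frame and expressed in percent. The literature's
wording mixes YFP/CFP and CFP/YFP; since binding of the signal (cAMP,
chloride) *decreases* FRET — donor up, acceptor down — the package default
emits the CFP/YFP-based series so responses read as positive percentages,
and the raw-FRET orientation is available as an option, with the choice
logged in pipeline metadata. No photobleach detrending is applied by
default (emulating pre-exposure stabilization); the generators can
nonetheless simulate bleaching so the consequences are testable.

ROI extraction from image stacks is out of scope by design — ROIs are
drawn manually in practice — so the input contract is a tidy CSV of
per-ROI traces.

## PDM colocalization

`compute_pdm()` evaluates, over an optional mask, the product of the
differences from the mean: PDM = (R − mean R)(G − mean G) per pixel.
Its mean over the mask equals the population covariance of the channels
(asserted to 1e−12 in tests); it is exactly invariant to adding a constant
to a channel and equivariant under scaling. Upstream, background is
estimated per slice by grayscale opening with a disc structuring element
(the morphological counterpart of rolling-ball estimation; default radius
50 px, recorded in run metadata — the method and radius are common-practice
choices, not prescribed ones) and Z-projection is per-pixel sum or max,
both supported and logged since figure-by-figure usage varies. Channel
means are taken over the projected mask rather than the full stack, because
the analysis operates on projections. Rendering uses a diverging
orange/purple palette symmetric about zero (±max|PDM|); the palette is
cosmetic and untested.

## What the generators emulate — and what they do not

* `simulate_dam_experiment()` draws each fly's sleep/wake sequence from a
  per-minute two-state Markov chain with light/dark- and phase-dependent
  transition probabilities; wake minutes emit Poisson counts, sleep
  minutes zero. Defaults: light p(w→s) = 0.03, p(s→w) = 0.07 (≈216 min of
  day sleep); dark p(w→s) = 0.15, p(s→w) = 0.03 (≈600 min of night sleep,
  mean bout ≈33 min); λ_wake = 3 counts/min — wild-type-like numbers with
  bouts long enough that the 5-min rule loses little. Effects are
  programmed by re-solving p(w→s) at fixed p(s→w) so the stationary sleep
  fraction changes by the target minutes (default −90 min/night for the
  experimental genotype during shift days), so ground truth is exact; the
  truth table reports both latent-state sleep and the 5-min rule applied
  to the latent runs, letting tests separate estimator error from
  scoring-rule behaviour. The chain has no circadian oscillator, no sleep
  homeostat, no rebound dynamics, and no anticipation — so passing tests
  demonstrate correct *accounting and inference*, not that real flies
  behave like two-state chains.
* `simulate_fluorescence_trace()` builds
  `F(t) = B·exp(−t/τ)·(1 + s·(A/100)·k(t)) + ε` with a double-exponential
  kernel normalized to 1 on the sampled grid (so noiseless recovery is
  exact at the kernel peak); FRET pairs get opposite polarity signs, giving
  a normalized-ratio peak of `100·((1+a)/(1−a) − 1)` for `a = A/100`. No
  motion, focus drift, or shot-noise scaling with intensity.
* `simulate_image_pair()` overlays shared and channel-private Gaussian
  blobs on a smooth gradient plus Gaussian noise, with per-pixel labels as
  ground truth. No optics model, no depth-dependent attenuation.

Determinism is part of the contract: identical seeds give bit-identical
outputs, emitted DAM text round-trips through the parser exactly, and
pipeline result folders are byte-identical across reruns (logs carry the
package version and a config hash, deliberately no timestamps).

## Numerical and degenerate-input choices

* ZT minutes live in [0, 1440) with half-open windows everywhere — ZT 720
  is the first dark minute — so no minute is double-counted.
* Mean episode duration of a window with no episodes, and activity while
  awake of a fully-asleep window, are missing values, never zero.
* Groups with fewer than two flies still yield point estimates but no SEM
  or p value.
* A PDM map with a constant channel is all-zero and flagged rather than an
  error; a mask must cover at least two pixels.
* The PDM float TIFF stores `(pdm/(2·scale)) + 0.5` with `scale` in the
  summary CSV, because TIFF values outside [0, 1] are not portably stored.
* The dead-fly filter (zero counts over the trailing 24 h, configurable)
  is standard actigraphy practice rather than a prescribed rule, and every
  exclusion is reported with its reason.

## Problem sizes used in the test and acceptance suites

Scoring equivalence is exhaustive over all 2¹⁶ binary 16-minute vectors
plus 10⁴ random full days; effect recovery uses 3 genotypes × 16 flies ×
4 days × 200 replicates; the type-I check uses 2000 null replicates at
n = m = 12; Mann–Whitney exactness enumerates all 252 five-versus-five and
20 three-versus-three splits. These sizes give the property checks
comfortable statistical resolution while keeping a full run of the suite
in the minutes range on one core.

## Known limitations

* The sleep scorer is single-beam: position within the tube, micro-
  movements below beam crossings, and multibeam monitors are out of scope.
* No circadian analysis (periodograms, phase estimation) and no
  sleep-depth/arousal-threshold assays.
* The Mann–Whitney exact path deliberately refuses ties; tied data fall
  back to the corrected normal approximation even in tiny samples.
* PDM is the only colocalization statistic offered — no Pearson/Manders/
  Costes suite, no segmentation, no automated cell counting.
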