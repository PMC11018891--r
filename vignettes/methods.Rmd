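---
title: "Models and methods behind eegpls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eegpls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eegpls` implements a complete pipeline for asking whether group-level
longitudinal EEG patterns — changes in functional connectivity and signal
complexity across treatment sessions — generalize to individual
participants. This vignette explains the models, the estimators, the
numerical choices, and what the synthetic-data validation does and does
not show.

## Connectivity: weighted phase lag index

For two channels with complex spectral coefficients $a$ and $b$, the
cross-spectrum is $X = a\,\bar b$; its imaginary part is nonzero only
when the channels' phases differ by something other than $0$ or $\pi$.
The weighted phase lag index over observations $k$ is

$$\mathrm{WPLI} = \frac{\lvert \sum_k \mathrm{Im}\,X_k \rvert}
                      {\sum_k \lvert \mathrm{Im}\,X_k \rvert} \in [0, 1].$$

Values near 1 indicate phase differences consistently on one side of the
real axis, with observations weighted by their distance from it; the
estimator therefore ignores zero-lag (volume-conducted) coupling and is
robust to lag/lead flips near the axis. We implement the
magnitude-weighted form rather than the debiased squared variant because
it matches the weighting description the measure is defined by.

Two observation schemes feed the same estimator:

* **Across epochs** (group analyses): per epoch and channel, tapered
  Fourier coefficients on a 0.5 Hz grid. Bins up to 30.5 Hz use a single
  Hanning taper (one observation per epoch); bins from 31 Hz use dpss
  multitapers with 2 Hz half-bandwidth — for 2-s epochs $NW = 4$ and
  $2NW - 1 = 7$ tapers, each taper contributing one observation. The
  default grid runs 1–50 Hz (99 bins): the 0.5 Hz bin would rest on a
  single cycle per epoch and is dropped; the grid is configurable.
  The dpss sequences are computed in-package via the standard symmetric
  tridiagonal eigenproblem and verified against an external reference.
* **Within epochs** (single-participant analyses): complex Morlet
  wavelets whose cycle count rises linearly from 3 at 4 Hz to 7 at
  50 Hz; frequencies below 4 Hz are excluded because three cycles no
  longer fit a 2-s epoch. Observations are within-epoch time points.
  Each wavelet is truncated at $\pm 3$ gaussian SDs and time points
  within half the wavelet support of either epoch edge are masked, so
  edge-distorted phase estimates never enter the sums. Averaging the
  per-epoch matrices over epochs gives a group-level analogue used to
  derive group patterns on the same grid as the individual analyses.

A denominator of exactly zero (all observations purely real) yields a
value of 0 with a flag rather than `NaN`, keeping feature matrices
complete; flags are carried through serialization.

## Complexity: multiscale entropy

Scale-$\tau$ series average non-overlapping blocks of $\tau$ samples
(trailing remainder discarded). Sample entropy with template length
$m = 2$ and tolerance $r = 0.5\,\mathrm{SD}$ is
$-\ln(A/B)$, where $B$ counts template pairs of length $m$ within
Chebyshev distance $r$ (self-matches excluded) and $A$ the same for
$m + 1$. Choices fixed here:

* $r$ is computed from the population SD of each epoch and channel's
  scale-1 series and held fixed across scales (the convention of the
  classic implementation); this makes the measure amplitude-invariant.
* The default coarsest scale is 20, leaving 50 points of a 1000-sample
  epoch — the minimum we accept for the template counts.
* Undefined values ($A = 0$ or $B = 0$) are masked, excluded from epoch
  averaging, never imputed.
* Sample entropy is not bounded by 1; we implement the standard
  definition, under which $-\ln(A/B)$ can exceed 1 (the $A/B$ ratio,
  not the entropy, lies in $[0,1]$).

The $O(N^2)$ template counting is implemented in C++; an independent
brute-force R implementation lives in the test helpers and the
acceptance script, and the two must agree exactly.

## Age as a confound

Both connectivity and complexity drift with age, and age differs between
outcome groups, so each feature column is regressed on participant age
by OLS before group inference — one pooled fit per column across both
groups and all sessions, which avoids re-introducing group differences
through group-specific fits. Residuals keep their original scale (the
column mean is added back). Within-person analyses need no such
correction: a constant age cannot confound session contrasts.

## Mean-centered task PLS-SVD

Group inference works on the matrix of (group x session) cell means,
centered per feature by the unweighted grand mean of the cell means.
This centering variant exposes group main effects, session effects and
their interaction together, which is what an omnibus
responder/non-responder-by-session analysis needs; within-group
centering is available by subsetting. SVD of the centered matrix gives
latent variables ordered by singular value; each LV's share of
crossblock covariance is $100\, s_i^2 / \sum_j s_j^2$. The sign of an LV
is fixed by making its largest-magnitude design salience positive.

* **Permutation test.** Each permutation shuffles session labels within
  every participant *and* reassigns participants to groups (preserving
  sizes), then repeats the full centering + SVD. We use the add-one
  estimator $p_i = (1 + \#\{s^{perm}_i \ge s_i\}) / (n_{perm} + 1)$: it
  is never zero and matches the "more extreme than 95%" decision rule.
  With the default 500 permutations the smallest attainable p is
  $1/501 \approx .002$; a stricter $\alpha = .001$ threshold therefore
  requires at least 999 permutations, and counts reported against it at
  default settings are honestly zero.
* **Bootstrap.** Participants are resampled with replacement within
  group. Replicate LVs are aligned to the original by orthogonal
  Procrustes rotation of the design saliences, the standard resolution
  of sign/order indeterminacy in this family. Bootstrap ratios divide
  the original loadings by the bootstrap SE of the aligned replicate
  loadings; $|BSR| > 2$ marks ~95% stability and $\ge 3.1$ ~99%.
  Brain-score condition means take percentile (2.5/97.5) intervals over
  replicates.
* **Follow-up gating.** Per-group follow-ups run when omnibus LV1 is
  significant and its saliences express a group-by-session interaction,
  operationalized as a non-constant group difference of the session
  salience profiles; follow-ups are judged at $\alpha = .025$
  (Bonferroni over two groups).

## Non-rotated PLS for individuals

For one participant, rows are epochs and conditions are sessions. A
predefined zero-sum contrast $c$ (unit-normalized) replaces the SVD:
loadings are $\sum_c c_c\,\bar x_c$ over grand-mean-centered condition
means, the singular value is their norm, and the salience vector is $c$
itself. With positive weight on week 1 in a `0 1 -1` contrast, a
decrease from week 1 to week 12 produces *positive* loadings — the sign
convention every downstream rule uses. Significance permutes epoch
labels across sessions (epochs are exchangeable under the null);
stability bootstraps epochs within session. Each contrast is evaluated
independently, without orthogonalization — the two complexity contrasts
(`1 0 -1`, `1 1 -2`) are deliberately non-orthogonal hypotheses.

## Similarity of individual and group patterns

The group pattern is the LV's singular image restricted to its stable
elements ($|BSR| > 2$; at least 10 elements required). When the source
is a rotated (SVD) analysis, the loadings are first sign-aligned with
the declared contrast, since the SVD sign convention is arbitrary with
respect to it. An individual counts as expressing the pattern only if
their non-rotated analysis is significant ($p < .05$) and their
saliences align with the group contrast; otherwise they are recorded as
showing no correlation. For the rest, Pearson r between group and
individual loadings over the stable mask is categorized:
$r \ge .4$ moderate-strong (boundary inclusive), $.1 < r < .4$ weak
positive, $-.1 \le r \le .1$ negligible, $r < -.1$ negative.

The visual-rating procedure of the original workflow is replaced by a
deterministic analogue: rules name a band/timescale window, a condition
contrast and a required direction; a change is "meaningful" when the
window holds at least a minimum fraction of stable elements and the mean
stable change exceeds 0.75 x the RMS of the window's centered condition
means. That reference scale is deliberately *not* the rule functional's
own RMS — a flat session profile must not be judged against its own
noise. Connectivity rules: responders show an alpha decrease and/or
beta increase from week 1 to 12, non-responders the reverse (either band
may be absent from a reduced grid). Complexity rules: responders show a
stable early coarse-scale decrease; non-responders no meaningful early
change but some late change.

## The synthetic cohort generator

The generator is first-class, tested code that defines the study
conditions: two groups (default 25/18), three sessions, two states,
63–113 2-s epochs per recording at 500 Hz on a 28-channel montage, and
ages drawn per group from truncated normals (responders younger, so the
age regression is genuinely exercised). Signals are sums of shared
sinusoids plus independent 1/f and white noise:

* **Connectivity effects** place one shared oscillator per 0.5 Hz step
  across the target band on each target pair, with a nonzero phase lag
  (default $\pi/2$) and a (group, session) coupling-strength profile.
  Strength scales the shared amplitude; because a narrow-band
  oscillator competes only with the noise in its own frequency bin,
  WPLI saturates once the amplitude clears the per-bin noise floor, and
  realistic profiles therefore use strengths in the responsive range
  (roughly 0.03–0.3 against unit broadband noise).
* **Complexity effects** shift the 1/f-vs-white mixing weight of target
  channels: more 1/f raises coarse-scale entropy. This is the axis along
  which coarse-scale complexity is controllable in this signal model.
* Effects can be restricted to one recording state, mirroring designs
  where connectivity and complexity changes are strongest in different
  states (eyes-closed vs eyes-open); the bundled example uses this to
  keep the week-1 alpha oscillator from leaking into the complexity
  analysis of the same recordings.
* A `deviant_fraction` assigns some participants the opposite group's
  profile, and an optional common zero-lag source stresses WPLI's
  volume-conduction insensitivity.

What passing tests on this generator show: the estimators measure what
they claim (verified against oracles and closed forms), the inference
machinery is calibrated (type-I error of the permutation test on null
cohorts) and powerful against injected structure, and the similarity
pipeline recovers planted individual-level ground truth. What they do
not show: performance on real EEG, whose sources are not a handful of
stationary sinusoids, whose noise is neither white nor exactly 1/f,
and which carries artifacts and nonstationarity the generator does not
emulate. Percentages observed on synthetic cohorts are properties of the
chosen signal-to-noise regime, not predictions for patient data.

## Problem sizes and numerics

The bundled `example_study()` replica — 12 + 9 participants, 8 channels,
250 Hz, 24–30 epochs per recording, a 2–20 Hz Fourier grid, a 6–14 Hz
Morlet grid, timescales to 10, 200 permutations and 200 bootstrap
replicates — is the package's own choice of a validation size at which
the full pipeline runs in minutes while keeping every inferential
stage non-trivial (the permutation floor $1/201$ sits well below the
.025 follow-up level). Full-size defaults (99 x 378 WPLI grids, 500
permutations) are simply the constructors' defaults.

Other numerical choices: population SD (divide by $N$) in the sample
entropy tolerance; denominator-zero WPLI flagged, never `NaN`;
permutation and bootstrap streams are seeded per stage and restore the
caller's RNG state; bootstrap replicates that would produce an empty
cell are redrawn (at most 10 attempts) — with within-group resampling
this is a guard, not an expected path; feature matrices serialize to
TSV with 17 significant digits for bit-exact round trips; cohort
containers store float32 payloads with JSON sidecars (no HDF5 dependency
is available to R here, so the container is a self-describing directory).

## Known limitations

* The Morlet edge mask trades data for unbiased phase estimates; very
  short epochs at low frequencies can lose most time points.
* Non-rotated permutation treats epochs as exchangeable across sessions;
  slow within-session drifts would violate that null.
* The rule-based rating is an analogue of, not a substitute for, human
  visual rating; its thresholds (stability, window fraction, 0.75 RMS)
  are package choices, documented and configurable.
* Group analyses require complete session data; there is no imputation.
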