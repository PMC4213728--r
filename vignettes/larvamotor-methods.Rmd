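---
title: "Methods: quantifying larval zebrafish locomotor phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying larval zebrafish locomotor phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvamotor)
```

`larvamotor` quantifies larval zebrafish locomotor phenotypes from four
kinds of tabular input: tracked body-point coordinates, extracellular
motor-nerve recordings (or pre-detected spike times), dose–survival
tables, and phenotype scoring counts. This vignette documents the models
and procedures, the tunable parameters and why their defaults are what
they are, the synthetic-data generators used for closed-loop testing, and
the places where a genuine design choice had to be made.

## Body-angle kinematics

### The angle

Three points are tracked per video frame: head H (between the eyes),
mid-trunk M (at the swim bladder), tail T (near the tip). The body angle
is the angle subtended at M:

$$\theta = 360 - \frac{180}{\pi}\,
\arccos\!\left[\frac{(H-M)\cdot(T-M)}{\lVert H-M\rVert\,\lVert T-M\rVert}\right]$$

A straight larva (tail opposite the head) has $\theta = 180^\circ$, the
resting posture, and the arccos range forces $\theta \in [180^\circ,
360^\circ]$: bending in either direction increases $\theta$. The
normalization makes $\theta$ independent of the distances of H and T from
M, so tracking jitter along the body axis does not move the angle; it is
also invariant under rigid rotation and translation of each frame (checked
to $10^{-9}$ degrees in the tests). Numerically, the arccos argument is
clamped to $[-1, 1]$: on exactly collinear frames floating-point round-off
can push the cosine a few ulps outside its domain, and the clamp turns
what would be NaN into an exact $180^\circ$ or $360^\circ$.

Because the arccos discards the bend side, direction is recovered from the
planar cross product $(H-M)\times(T-M)$: positive means a left-directed
excursion, matching the convention that left movements plot above the
resting line. Historically this judgement was made by replaying video;
automating it is a deliberate extension, and its correctness is pinned by
a mirror-symmetry property: reflecting all x-coordinates flips every
event's direction and changes nothing else.

### Events

An event spans from the frame $\theta$ leaves a rest band until it
re-enters it while moving in a single direction. Parameters:

* `rest_band` (degrees, default 5): half-width of the band about
  $180^\circ$. "Close to 180°" is not a quantified notion in this
  literature; $\pm 5^\circ$ comfortably exceeds tracking jitter at
  typical magnification while sitting far below the smallest wag peaks.
  Exit and re-entry use the same threshold (no hysteresis gap) so that
  event boundaries are unambiguous.
* `min_duration` (frames, default 3): excursions above the band for fewer
  frames are discarded as tracking noise; at 300 fps this is 10 ms, half
  the shortest behaviorally meaningful beats.

Classification is by peak angle: **wag** below $200^\circ$, **LAM**
strictly between $200^\circ$ and $270^\circ$, **extreme** at $270^\circ$
or above. The LAM definition uses strict inequalities, so ties resolve
away from the LAM class: a peak of exactly $200.0^\circ$ is a wag and
exactly $270.0^\circ$ is extreme. Extreme events are reported but never
enter LAM statistics — the source phenotype definitions are silent about
them, and mixing them in would bias duration summaries.

Durations are rest-to-rest ("from the initial resting state ... and return
back to the original position"): onset is the last in-band frame before
the excursion and offset the first in-band frame after it. On synthetic
half-sine excursions this recovers scheduled durations to within one frame
period (3.33 ms at 300 fps). Two degenerate cases are handled explicitly:
an excursion still above the band at either edge of the trace is flagged
`truncated` — it is counted but excluded from duration statistics, since
its true duration is unknowable; and an excursion whose signed angle
changes side without reaching rest is split at the direction change and
flagged `split`, because the single-direction duration definition does not
cover it. Splitting at signed-angle zero crossings is our choice; how such
events were historically divided is not recorded.

Summaries (`summarize_events()`) count LAMs per half-open window
(default 20 s, the standard recording length), report duration means with
s.e.m., and expose the right-continuous empirical CDF of LAM durations —
the standard way to compare duration distributions across phenotypes.

## Fictive motor patterns

Spikes are detected from a voltage trace by rising-edge threshold crossing
with a refractory interval (default 1 ms, well under any physiological
ISI here). The automatic threshold is median + 5 × MAD/0.6745 — a robust
five-sigma rule — because the threshold historically used in acquisition
software is unreported; a constant trace has no detectable activity and is
an error rather than an empty result. With pre-detected spike times the
detector is bypassed entirely.

Segmentation is a single left-to-right pass over inter-spike intervals:

* ISI < `intra_burst_isi_max` (default 10 ms): same burst;
* `intra_burst_isi_max` ≤ ISI ≤ `episode_isi_max` (default 100 ms): new
  burst, same episode;
* ISI > `episode_isi_max`: new episode.

The published bands ("<10 ms" and "between 10 and 100 ms") leave exactly
10 and exactly 100 ms undefined; we resolve them as *same burst iff
ISI < 10* and *same episode iff ISI ≤ 100*, and both bounds are
arguments. A lone spike is a burst of one with duration zero — the
duration definition (last minus first spike) forces this — and such bursts
are included in spikes-per-burst statistics. The pass is checked against a
pairwise $O(n^2)$ grouping oracle on 1000 random spike trains in the
acceptance suite.

Metrics: spikes per burst; burst duration; burst period = time between
successive burst start times, computed **within episodes only** (a period
spanning an inter-episode gap of > 100 ms would conflate quiescence with
cycle period, so an episode with a single burst contributes no period —
the field is NA, never 0); bursts per episode.

## Group statistics

* `chi_square_counts()`: Pearson chi-square without continuity correction
  by default (the correction is conservative for the 2 × C tables here and
  historic analyses of this kind did not apply it). Two layouts: pooled
  (batches collapsed; 2 conditions give df = 1) and condition-by-batch
  stratified. Published two-condition comparisons of this phenotype report
  df = 3, which a pooled 2 × 2 cannot produce; since the exact construction
  is not described, both layouts are offered and pooled is the default.
  A zero row or column margin is an error (the statistic is undefined).
* `rank_sum_bonferroni()`: Wilcoxon rank-sum per requested pair (exact for
  small tie-free samples, normal approximation otherwise), with
  $p_{adj} = \min(1, m\,p)$ and $m$ = number of requested pairs — the
  historical analyses do not state their $m$, so it is simply the number
  of comparisons the caller asks for. Exactness is verified against full
  enumeration of all $\binom{n_1+n_2}{n_1}$ assignments up to
  $n_1+n_2 = 12$.
* `kruskal_wallis()`: tie-corrected H against a chi-square reference; all
  observations identical gives H = 0, p = 1 (not an error).
* `gated_paired_test()`: the gate used for paired ROI-intensity data.
  Each group is screened with a Lilliefors test — the KS distance to a
  normal with estimated mean and sd — whose p-value is Monte-Carlo
  (default 10,000 replicates under a fixed internal seed, so results are
  reproducible and the caller's RNG stream is untouched; the classical
  Lilliefors table is itself an approximation). All groups normal at
  $\alpha = 0.05$ (the conventional level; the historical gate level is
  unstated) → one-way repeated-measures ANOVA with subject as error
  stratum; otherwise → Friedman. A constant group cannot be screened and
  routes to Friedman; fully identical paired columns return p = 1 under
  either branch. One historical mention of "Fisher's test" for normality
  is an unusual usage we do not reproduce; the Lilliefors gate is applied
  uniformly.
* `lc50_estimate()`: the default is log-linear interpolation between the
  two doses bracketing 50% survival — it honors an exactly-observed 50%
  point (returning that dose), is scale-equivariant in dose, and matches
  how an LC50 is read off a survival curve without asserting a model. When
  the lower bracket is dose zero the segment falls back to the natural
  scale (log 0 is undefined). The alternative is a two-parameter logistic
  (binomial GLM on log-dose; zero-dose rows are dropped for the same
  reason) with a delta-method standard error.

## The synthetic-data generators

The generators define the conditions under which the pipeline is tested;
they are first-class, validated code, not fixtures.

**Trajectories** (`simulate_trajectory()`): H and M fixed (the head is
embedded in agarose in this preparation), T reconstructed on the unit
circle about M — distance does not affect $\theta$, so unit distance keeps
the geometry minimal. The angle is a small rest jitter (folded-normal
magnitude, sd 0.5°, a random side per frame) plus scheduled half-sine
excursions. Half-sines make the rest-to-rest duration definition exactly
well-posed on synthetic data: the excursion leaves and returns to rest
smoothly with a single interior peak. Event counts are Poisson (the
simplest model for spontaneous plus sparse evoked events), placements
uniform with overlap rejection (falling back to random gap allocation when
the window is crowded; an error only when the requested events genuinely
cannot fit). Durations are truncated normal with a 5-frame floor (so every
scheduled event survives the detector's minimum-duration filter), peaks
uniform within class bands kept ≥ 5° clear of the class boundaries, and
laterality is alternating, unilateral or mixed. Presets encode the three
phenotypes with the published group means: control — 13.2 LAMs per 20-s
window of 57 ms mean duration, alternating; Mn-treated — 2 LAMs of
163.4 ms, unilateral, sparser wag clusters; recovered — 15.3 LAMs of
54.7 ms. Wag durations are 39.8 ms (control-like) vs 36.9 ms (Mn-like).
Only group means ± s.e.m. were ever published, so the distribution family
(truncated normal, sd 10 ms for control-like and 30 ms for Mn-like LAMs)
is a modeling choice, not a reproduced fact.

**Spike trains** (`simulate_spike_train()`): Poisson number of episodes at
`episode_rate` per minute placed with inter-episode gaps > 110 ms; bursts
within an episode at truncated-normal periods; spikes evenly spaced within
a burst. Draws are truncated so the generated ground truth always
satisfies the segmentation's own ISI bands (intra-burst < 10 ms,
inter-burst gaps strictly inside 10–100 ms) — parameter sets that cannot
satisfy them (e.g. burst duration ≥ period) are rejected up front. The
numeric defaults (control-like: ~35 ms period, 10 ms duration, 3–5
spikes/burst; Mn-like: ~70 ms period, 25 ms duration, more spikes) are
invented plumbing: published figures plot these metrics but print no
values, and only the phenotype contrast (longer, slower bursts under Mn)
is treated as a constraint. The optional voltage trace is gaussian noise
plus a sharp-onset kernel at each spike so a rising-edge detector fires at
the spike sample.

**Survival** (`simulate_survival()`): expected survival
$1/(1+(d/\mathrm{LC}_{50})^{h})$ — exactly 0.5 at the LC50 — with binomial
counts. Defaults: LC50 2 mM, doses spanning 0.2–10 mM as in a
dose-ranging series, 20 larvae per dose. The Hill slope $h = 4$ is a
modeling choice (a moderately steep acute-toxicity curve); no slope was
ever published.

**Behavior counts** (`simulate_behavior_counts()`): binomial counts per
batch (3 batches of 20 larvae). Sideways-floating and curved-spine
probabilities are the published proportions (98%/65% Mn-treated, 12%/27%
recovered, 0 in controls); the circling probabilities are read off
published trends rather than printed values and are config-overridable.

All generators derive deterministic substream seeds from one user-facing
integer seed and are bit-reproducible given (params, seed).

### What the generators do and do not emulate

They reproduce the *statistical structure* the analyses assume: event
sparsity and clustering, class-separated peak angles, rest-to-rest
half-sine excursions, nested ISI bands, logistic dose–response, binomial
scoring. They do not emulate tracking artifacts (point swaps, dropouts,
pixel quantization), body-axis curvature beyond the three-point abstraction,
amplitude variability or electrode drift in voltage traces, overdispersed
batch effects, or stimulus timing (taps are not timestamped in this kind
of recording, so all detected events are counted regardless of
provenance). Passing closed-loop tests therefore demonstrates that the
analysis recovers what it claims from data with the assumed structure —
not that it is robust to every failure mode of real video tracking.

## Problem sizes and test design

The closed-loop suites use 20 recordings per preset for kinematic and
fictive parameter recovery (sample means within 2 s.e.m. of the generator
rate and within 10% of generator duration means), 200 seeds for the
duration-contrast power checks at n = 50 per group, 50 seeds for LC50
recovery (median within ±0.25 mM of 2 mM), and 1000 random spike trains of
up to 200 spikes against the segmentation oracle — sizes chosen so each
property is measured with comfortable statistical margin while the whole
suite runs in a couple of minutes on one CPU.

## Interfaces

All user-facing functions take and return tibbles (or small lists of
tibbles with `tidy()`/`glance()` methods), so stages chain with the pipe.
File formats are deliberately plain text: comma-separated tables for
tracks (`frame,Hx,Hy,Mx,My,Tx,Ty`), traces (`time,voltage`), survival and
count tables; one spike time per line; structured `key: value` reports for
summaries and the per-run manifest. No binary container is implicated by
these data kinds, and plain text keeps every input human-auditable.
`run_pipeline()` executes simulate → kinematics → fictive → stats for the
selected presets and writes a manifest recording the package version, the
seed and every tunable; reruns with an identical config are
byte-identical. A thin command-line wrapper over `run_pipeline()` ships in
`inst/scripts/run_pipeline.R` for shell use; the R functions are the
primary interface.

## Known limitations

* The detector assumes the rest band is meaningful; systematic tracking
  bias that shifts the baseline angle would need the optional 3-frame
  median smoothing and/or recalibration of `rest_band`.
* Weak wags whose peaks barely clear the rest band are detected with
  onset/offset inside the true excursion, so wag durations are
  systematically shortened relative to rest-to-rest truth; LAM durations,
  the quantity of scientific interest, do not suffer measurably from this
  (they are recovered within a frame period).
* Multi-peak excursions are split by signed-angle zero crossing, which
  undercounts nothing but may split a single biomechanical beat that
  grazes the midline.
* Endpoint survival only: no survival-time modeling.
* The stratified chi-square layout treats batches as independent rows; it
  is a transparency device, not a mixed-model treatment of batch effects.
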