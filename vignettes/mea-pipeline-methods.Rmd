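---
title: "Methods: MEA spike-train analysis for developmental neurotoxicity screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA spike-train analysis for developmental neurotoxicity screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

meadev implements the analysis chain used in chronic-exposure developmental
neurotoxicity (DNT) screens on multi-well microelectrode arrays (MEA):
rat cortical cultures grow on 48-well plates with 16 extracellular
electrodes per well, spontaneous activity is recorded for 30 minutes on
days in vitro (DIV) 7, 10, 14, 17, 21, 24 and 28, wells are chronically
exposed to a compound from DIV 7 onward, and per-well activity parameters
are turned into developmental dose-response curves. This vignette documents
the models, the defaults and the numerical choices; the README shows the
worked example.

## Detection chain

**Spike detection (optional front end).** The canonical input is a spike
list, but raw extracellular traces (12.5 kHz) can be processed with the
same contract commercial systems use: a 200–5000 Hz band-pass
(2nd-order Butterworth, applied forward and backward so it is zero-phase;
the trace is centred first to avoid edge transients), a robust per-electrode
noise estimate, and threshold crossing at 7 × SD in either polarity with the
spike timestamp at the extremum of a 2.4 ms pre / 3.6 ms post window and a
dead time of 3.6 ms. The noise SD is a rolling median-absolute-deviation
estimate (MAD/0.6745, 10 s windows, median across windows): a rate of even
several spikes per second occupies a tiny fraction of samples, so the MAD is
essentially unaffected by spikes, which a plain SD is not. The exact
adaptive-threshold schedule of the commercial detector is proprietary; this
stage is a documented, testable equivalent, not a bit-level reproduction.
Electrodes enter the analysis only if they record at least 6 spikes per
minute (inclusive).

**Burst detection.** A burst is a cluster of spikes on one electrode that is
improbable under a Poisson null: its *surprise* is
$S = -\ln P(X \ge n)$ with $X \sim \text{Poisson}(r\,T)$, where $n$ is the
cluster's spike count, $T$ its duration and $r$ the electrode's mean rate.
The mean rate uses the full analysis window (the observation period), not
the span of the spikes. Surprise is evaluated in the log domain
(`ppois(..., log.p = TRUE)`), so values far beyond 700 nats are exact;
"10 surprises" means $S \ge 10$ nats, the conventional scale of the
surprise method. The search seeds candidates on runs of at least two
consecutive inter-spike intervals below half the mean ISI, extends the right
edge while $S$ strictly increases (10-spike lookahead), trims the left edge
the same way, iterates to a fixed point, and then maximizes $S$
exhaustively over a bounded neighbourhood of the converged candidate —
a cheap refinement that removes the local optima a pure greedy edge walk
can get stuck in. A final merge pass collapses adjacent accepted bursts
whenever their union is more surprising than either part, so two dense
clusters separated by a short lull are reported as the single, more
improbable event they jointly form. Accepted bursts need $S \ge 10$ and at
least 3 spikes
(both configurable), are disjoint, and are reported in time order. The
package also ships `brute_force_bursts()`, an exhaustive enumeration over
all contiguous subsequences with greedy acceptance by descending $S$; it is
quadratic and exists purely as an independent oracle for the test-suite,
where the two routes are required to agree.

**Network-burst detection.** Spikes of all analysed electrodes of a well are
pooled and sorted; maximal runs in which every consecutive gap is at most a
well-adaptive maximum interval become candidates. The adaptive interval is
$C / r_{\text{well}}$ with $C = 0.25$ and $r_{\text{well}}$ the pooled spike
rate, clamped to 5–300 ms: busy wells must be more coincident than sparse
ones. The published description of the commercial rule states only that the
threshold adapts to the well's mean spike rate; the inverse-rate form with
clamping is this package's documented dialect, with all constants exposed in
`network_burst_config()`. A candidate is accepted iff it has at least 40
pooled spikes and at least 15% of the analysed electrodes contribute a
spike; "minimum of 15%" rounds up (3 of 16), participation means
contributing at least one spike, and the denominator is the set of
electrodes that passed the activity filter — physically present but silent
electrodes cannot participate.

## The ten parameters

Per well and recording day, over the last 20 minutes of the 30-minute
recording (the most stable stretch): pooled spike count, burst count,
network-burst count, mean burst duration, mean network-burst duration, mean
inter-burst interval (end of one burst to the start of the next on the same
electrode, pooled across electrodes), mean spikes per burst, mean spikes per
network burst, mean ISI within network bursts (a network burst's span over
its spike count minus one, averaged across network bursts), and synchrony.
Counts are pooled well sums rather than per-electrode means; the
normalization stage divides them by a control value, so the scale convention
cancels, and pooled sums keep silent electrodes from diluting the signal.
Any mean over an empty set is `NA` — a well without network bursts has an
undefined network-burst duration, not a zero — and `NA`s are excluded
pairwise downstream, never imputed, because imputing zeros would fabricate
hypo-excitation.

**Synchrony.** For every unordered pair of analysed electrodes with at
least 10 spikes each, the cross-correlogram over lags up to ±100 ms
(5 ms bins) is summed and normalized by $\sqrt{n_x n_y}$, which makes the
zero-lag peak of two identical trains exactly 1; the well score is the mean
over pairs, clamped to [0, 1]. Under independence the expected pair score is
$\sqrt{n_x n_y}\, 2w / T$ (lag half-window $w$, duration $T$), which the
tests verify against simulation. The estimator saturates at 1 for strongly
recruiting cultures — with the default generator most spikes sit inside
co-active volleys, so control wells score 1. Sensitivity analyses of the
synchrony metric therefore use lower recruitment fractions, where the score
is informative; this is a property of the (deliberately simple, published)
normalization, and the clamp boundary is where a real screen would observe
ceiling effects too.

## Normalization and statistics

**Well inclusion.** A well enters an experiment only with at least four
bursting electrodes at the DIV 7 baseline; the decision is made once and
applies to all of the well's recording days.

**Cumulative treatment ratios.** Raw per-well values are summed over
recording days from DIV 7 up to each DIV (cumulative approach), and every
cumulative value is expressed as a percentage of the mean cumulative value
of the *same-sex* solvent-control wells at DIV 28. Sex-matched controls are
used because male and female cultures are normalized and plotted separately
throughout. The order of operations is: cumulate, normalize provisionally,
exclude outliers per condition and DIV, then renormalize the controls so
the retained control mean at DIV 28 is exactly 100% — this guarantees the
printed identity ("the control curve ends at 100%") at machine precision
regardless of which control wells the outlier rule removes. Because raw
parameters are non-negative, every well's cumulative curve is monotone.

**Outlier exclusion.** Within each (parameter, compound, concentration,
sex, DIV) group, values farther than 2 sample SDs from the group mean are
flagged, in a single pass with no re-iteration — the simplest literal
reading of the rule. Groups smaller than 3 are never flagged (their SD is
unstable). The rule is applied to ratio values; whether the original
procedure flagged ratios or raw cumulative values is not recoverable from
its description, and ratios keep the rule scale-free across parameters. On
normally distributed groups of the study's sizes (12–32 wells) this rule
removes a little under 4% of values; the acceptance script recomputes that
rate.

**Benchmark response (BMR).** The band around the control curve is the
control mean ± the SD of the retained control ratios pooled across
experiments and sexes at each (parameter, DIV) — "average variation of the
pooled controls" made concrete. Ratios are already sex-normalized, so
pooling sexes on the ratio scale is coherent. A `time_averaged` mode
(per-parameter mean of the per-DIV SDs) is available. Statistically
significant deviations smaller than the band are reported but not counted
as effects.

**ANOVA and flags.** Development of control cultures is compared with
one-way ANOVA and Tukey HSD (`aov` + `TukeyHSD`). Compound effects use a
two-way fixed-effects ANOVA (concentration × sex) per parameter and DIV
with Type-II sums of squares (`car::Anova`), because well counts per
condition (12–32) are unbalanced and Type-II is invariant to factor
ordering. Tukey-adjusted contrasts of each concentration against control
are taken within sex (the Tukey family is all pairwise concentration
comparisons within a sex), and the sex contrast within each concentration
measures sex specificity; with two sexes that family is a single
comparison per concentration. A cell is *significant* iff its adjusted
p ≤ 0.05 *and* its deviation from the sex-matched control mean exceeds the
BMR half-width; its direction is excitation (above control) or inhibition
(below). The lowest concentration with any significant cell across
parameters and DIVs is the compound's LOEC per sex; "no effect" otherwise.
The DIV 7 baseline (pre-exposure) is excluded from testing by default. No
multiple-testing correction is applied across parameters or DIVs, matching
the original procedure, which corrects only within the Tukey families.

## The synthetic generator

No recordings are publicly deposited, so the package ships a generator
whose defaults encode the study conditions: 48-well plates, 16 electrodes
per well, 30-minute recordings on DIV 7–28, activity starting at DIV 4,
every well active by DIV 7, and a stable plateau from DIV 10. The
developmental ramp is a raised cosine between onset and plateau — only the
endpoints and monotonicity are contractual, and a smooth interpolant avoids
spurious kinks at the boundary days; halfway through the ramp (DIV 7 for
the 4→10 default) the multiplier is exactly 0.5.

Activity is a doubly stochastic point process: well-wide network-burst
events arrive as a homogeneous Poisson process (4 events/min at plateau);
each event recruits every electrode independently with probability 0.6;
each recruited electrode fires a Poisson volley (40 spikes/s over a
log-normal duration, median 0.3 s, log-SD 0.4) with ~10 ms Gaussian onset
jitter; and each electrode adds tonic background firing (0.3 spikes/s).
These rates are order-of-magnitude choices for cortical cultures on
commercial 48-well plates — the source study publishes no absolute rates —
and they put the derived metrics (≈0.8 spikes/s per electrode, a few
bursts per electrode per minute, ≈13 spikes per burst, ≈100 spikes per
network burst) in the range typical of such cultures; all are `sim_config()`
fields, not constants. Well identity is a log-normal rate multiplier
(CV 0.2) drawn once per well and shared across DIVs, so wells are
consistently strong or weak across development, which is what makes
cumulative ratios behave like repeated measures of the same culture.

Two structured deviations are built in. Male wells get +25% on the
network-burst rate over DIV 10–17 only, mirroring the qualitative
male–female difference reported for developing control cultures; within
each sex, control activity is stationary from DIV 10. Compound effects are
multiplicative factors on the generative knobs (network-burst rate,
within-burst rate, volley duration, recruitment, background, jitter) that
switch on at a hard onset DIV, optionally in one sex — the simplest
mechanism reproducing effects that "appear after 1–2 weeks of exposure".
A gradual accumulation model would be more physiological but cannot be
constrained by the published observations.

Randomness is organized as one substream per (seed, plate, well, DIV),
derived by integer hashing, so a dataset is byte-reproducible from its
config and seed, and adding wells or days never perturbs existing ones.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no biophysics (no conductance-based neurons, no
GABA switch, no receptor pharmacology), no electrode-level waveform or
noise structure, no plate or isolation batch effects beyond the per-well
multiplier, no gradual onset or recovery dynamics, no cytotoxicity, and
compound "mechanisms" are whatever multipliers the user injects. The suite
demonstrates that the *analysis* recovers what the generative model puts
in; it cannot validate biological claims.

## Numerical choices and problem sizes

* Poisson tails via `ppois(log.p = TRUE)`; candidate pruning in the burst
  scan uses the exact bound $P(X \ge n) \ge e^{-\lambda}\lambda^n/n!$, so
  pruning never changes a decision, only skips tail evaluations that cannot
  win. A zero-duration cluster is capped at $S = 10^9$.
* Ties during burst extension/trimming keep the shorter burst (strict
  improvement is required to move an edge).
* The 15% electrode floor rounds up (`ceiling`); the 6 spikes/min and
  4-bursting-electrode floors are inclusive.
* Degenerate inputs: empty or singleton trains yield empty burst lists
  (not errors); a well with no spikes yields no network-burst analysis;
  zero-variance outlier groups flag nothing; ANOVA cells that are empty are
  dropped with a warning, and a p-value that cannot be computed (zero
  residual variance) is never counted as significant.
* Test problem sizes: oracle-equivalence runs use 1000 random trains of up
  to 100 spikes (where exhaustive enumeration is exact and fast);
  end-to-end recovery uses 50 replicates of a 48-well plate (12 wells per
  concentration × sex, the study's minimum group size) across all seven
  recording days, with a +50% network-burst-rate effect injected in one sex
  from DIV 14; null calibration pools six control-vs-control plates. These
  sizes were chosen as the smallest designs that match the study's group
  sizes and give stable pass/fail behaviour for the stochastic checks.

## Known limitations

The burst scan is a (refined) local optimizer: on adversarial trains it can
differ from the exhaustive oracle, which is why oracle agreement is stated
as a rate over random trains rather than an identity. The adaptive
network-burst interval and the synchrony normalization are documented
dialects of proprietary definitions. The two-way ANOVA treats wells as
independent within each DIV and parameter — cumulative ratios are
correlated across DIVs by construction, so per-DIV tests are not
independent across DIVs (the original procedure shares this property). The
BMR band is descriptive (1 SD), not a formal benchmark-dose model; no BMD
curve fitting, mixed-effects modelling, or cross-parameter multiplicity
correction is attempted, by design.
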