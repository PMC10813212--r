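---
title: "Methods: quantifying sleep-state misperception from polysomnography and diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying sleep-state misperception from polysomnography and diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

People with insomnia often report sleep that differs sharply from what a
polysomnogram (PSG) records: they overestimate how long it took them to
fall asleep and underestimate how long they slept. This discrepancy —
sleep-state misperception (SSM) — is clinically meaningful in its own
right, and the hyperarousal account of insomnia predicts that it should
track electrophysiological signs of residual cortical activation: alpha
rhythm persisting through the sleep-onset period, unstable wake/N1
dynamics while falling asleep, and fragmented REM sleep.

`ssmpipe` implements the full analysis chain needed to test those
predictions on single-night PSG + sleep-diary data: misperception
indices, automated stand-ins for visually scored EEG measures,
Markov-chain transition analysis of the sleep-onset window, and a
nonparametric statistics layer — together with a synthetic-cohort
generator with known ground truth, so that every stage is testable
without access to patient recordings (which typically cannot be
archived publicly).

## Misperception indices

For each subject-night the package computes, from the diary (subjective)
and the hypnogram (objective):

* `SLm = (SL_subj / SL_obj) x 100` — sleep-latency misperception; values
  above 100% are overestimation. Undefined when `SL_obj = 0` (sleep in
  the first epoch); such subjects are excluded from SLm analyses with a
  logged warning rather than imputed.
* `TSTm = (TST_subj / TST_obj) x 100` — total-sleep-time misperception;
  values below 100% are underestimation.
* the raw discrepancy `SL_subj - SL_obj` (minutes), which splits the
  sample at a 10-min cutoff into LOW and HIGH discrepancy groups. Ten
  minutes is the shortest uninterrupted sleep period people reliably
  recognize as sleep, so smaller discrepancies are compatible with
  chance. A discrepancy of exactly 10 min goes to LOW (the published
  rule states `<10` and `>10` and leaves equality unassigned; the
  package needs a deterministic rule and makes it configurable).

Indices are carried at full precision; rounding to two decimals happens
only in report tables (`report_round()`).

## Time conventions

All quantities share a single time origin: bedtime (BT), the moment the
subject starts trying to sleep. Epoch `i` (0-based) of the 30-s hypnogram
covers `[30 i, 30 (i+1))` seconds from BT; windows are half-open and an
epoch belongs to a window iff its start time does. Latencies are
therefore reported at 0.5-min resolution — the scoring raster itself
claims nothing finer. Under a single origin the objective sleep latency
is identically the latency to the first non-wake epoch; summary tables
in the clinical literature sometimes print a mean "sleep latency"
shorter than the mean latency-to-N1, which is impossible under one
shared origin and usually signals that two different anchors were mixed.
The package refuses that ambiguity: one anchor, one definition. WASO is
wake between the first and last sleep epoch by default (extendable to
end-of-recording by option), and the number of awakenings is the number
of maximal wake runs in that span.

Diary clock arithmetic crosses midnight (BT 23:30 + 40 min = 00:10), and
every internal duration is minutes-from-BT, so no downstream computation
touches clock times.

## Automated stand-ins for visual scoring

The source measures are visually scored; visual scoring is not
reproducible by a program, so the package defines deterministic
operators with every threshold exposed as a parameter. They are
validated by recovery of scheduled events injected into synthetic
signals, not by agreement with any human scorer — passing tests show the
operators are faithful to their stated rules, not that they replicate a
particular scorer's judgement.

### Alpha density (%alpha)

Occipital channels (O1, O2) are band-limited to 8–13 Hz; the
instantaneous amplitude envelope (analytic-signal magnitude) is
thresholded at `k = 2` times a robust baseline; a 3-s micro-epoch is
alpha-positive when at least 50% of its samples (1.5 s) exceed the
threshold on either occipital lead (OR across leads, matching a scorer
who calls alpha when seen on either; AND is available). The alpha
density is the proportion of positive micro-epochs in the objective
sleep-latency window.

The baseline estimator matters more than `k`. A plain median of the
envelope fails when alpha occupies most of the window: the median then
tracks the bursts, the threshold rises above them, and density is
underestimated exactly where it is highest. The default is therefore a
two-pass estimator: an initial threshold at `k` times a low quantile
(default 0.05) of per-micro-epoch median envelopes flags clearly
alpha-positive micro-epochs; the baseline is then re-estimated as the
median envelope over the remaining (alpha-negative) micro-epochs. As
long as at least ~10% of micro-epochs are alpha-free, the second-pass
baseline reflects the noise floor, and recovery holds across burst
coverages from 0 to 0.9 (tested at envelope SNR 3). Because the
threshold is relative, labels are invariant to any common rescaling of
the channels — no microvolt calibration is assumed.

Alpha density is reported both as a proportion and as a percent, and
every downstream formula states which scale it uses. This redundancy is
deliberate: on bounded quantities, scale mixups are easy to make and
hard to see (a reported SD exceeding the feasible maximum for the stated
mean of a bounded variable is the classic symptom), so the package never
leaves the scale implicit.

### K-complex detection and latency

On frontal leads (F3, F4), band-limited to 0.5–4 Hz: a candidate is a
trough below −40 µV immediately followed by a positive component; event
boundaries are the surrounding baseline crossings; candidates are kept
when the total duration is 0.5–3 s and the peak-to-peak amplitude is at
least 75 µV. Events overlapping across the two leads merge (earliest
start wins). The amplitude gate is applied as `>=` 75 µV — the canonical
direction for K-complex scoring — although one also finds it printed as
`<=` in the applied literature; the direction and value are
configurable, and the package does not guess beyond making the gate
explicit. The first event's onset, in minutes from bedtime, is the
latency-to-first-K-complex.

### REM arousal density (A-REMd)

Within REM epochs of the paired hypnogram: an arousal is an abrupt EEG
frequency shift — rise of the smoothed envelope summed over 4–11 Hz and
16–45 Hz to at least twice its REM-window median — lasting at least 3 s,
with a chin-EMG amplitude elevation of at least 1 s inside the shift,
preceded by at least 10 s of sleep containing no other detected arousal.
The 11–16 Hz band is excluded from the shift criterion so that
sleep-spindle-frequency activity cannot satisfy it; this implements the
spindle exclusion as a frequency notch rather than a spindle detector,
which no part of the analysis otherwise needs. A-REMd is the proportion
of REM epochs containing at least one arousal onset, kept on the [0,1]
scale — the only scale on which a TSTm regression coefficient near −56
is dimensionally coherent with a mean near 0.38.

## Markov analysis of the subjective sleep-onset window

Within `[0, SL_subj)` — the window in which the subject believed
themselves still awake — consecutive epoch pairs are counted over the
fixed state space {W, N1, N2, N3, REM} and row-normalized to the
maximum-likelihood transition matrix. Two conventions are load-bearing:

* A from-stage never visited in the window yields a **missing row, not a
  zero row**. Imputing 0 would conflate "never left N1" with "never
  reached N1"; exclusion counts are reported per comparison so either
  convention can be audited.
* The state space stays fixed at all five stages even when (as is
  typical at sleep onset) N3 and REM are never reached; absent stages
  appear as missing rows.

The first-order (memoryless) assumption is defended only within the
sleep-onset window, where instability dominates; the package deliberately
offers no whole-night transition analysis or higher-order chains. The
group contrast of interest is `P(N1 -> W)`, the probability of falling
back to wake from the lightest sleep stage, compared between
discrepancy groups by the exact Mann–Whitney test.

Because a [0,1]-bounded probability with mean near 0.5 cannot have an SD
near 0.7, published summaries of this quantity are occasionally
internally impossible; the package reports per-group mean, SD, and the
exclusion counts together so its own summaries stay checkable.

## Statistics layer

* **Mann–Whitney U** with midrank ties. For `min(n1, n2) <= 8` the
  two-sided p is exact, by enumerating the permutation distribution of U
  over all group assignments of the observed midranks (for tie-free data
  this is the classical exact U null; with ties it is the exact
  conditional null). Larger samples use the normal approximation with
  tie and continuity corrections. The **rank-biserial** effect size is
  `r = 2 U1 / (n1 n2) - 1` with the comparison group first; the group
  order is an explicit argument (default LOW first), since the sign is
  meaningless without it.
* **Spearman's rho** as the product-moment correlation of midranks;
  exact permutation p for `n <= 8` (full `n!` enumeration), t
  approximation otherwise.
* **Shapiro–Wilk gate** (`stats::shapiro.test`) flags each analysis
  variable; the pipeline's group comparisons and correlations are
  nonparametric throughout, which the gate documents rather than
  decides (with n = 16 and ratio-scale indices, normality essentially
  never holds).
* **OLS** via `stats::lm`, returning coefficients, R², adjusted R²,
  overall F and per-term p; rank-deficient designs are an error naming
  the collinear terms.
* **Backward-stepwise selection** for the TSTm model (predictors:
  A-REMd, alpha density, N3 latency). Two removal criteria are
  implemented. The default, matching the adjusted-R² model-comparison
  logic commonly reported, greedily removes the predictor whose removal
  most increases adjusted R² and stops when none does. That rule retains
  a null predictor whenever its |t| exceeds 1 — about 32% of the time
  under the null — which is a property of adjusted R², not a bug. When
  the goal is demonstrating exact-model recovery, the p-value rule is
  appropriate: remove the worst predictor while its p exceeds
  `p_remove`. A null predictor then survives with probability
  `p_remove`, so the recovery experiments use `p_remove = 0.01`,
  giving an expected exact-selection rate of 99% per null predictor;
  0.05 would sit exactly on a 95% target and turn the check into a coin
  flip.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` emulates the study design the pipeline targets: 16
single-night recordings, half low- and half high-discrepancy.

* **Hypnograms**: two-segment Markov sampling — a sleep-onset chain for
  the first 40 min (80 epochs), then a fixed whole-night chain (8 h
  total). The groups differ in the onset chain's N1→W return
  probability, jittered per subject (LOW: U(0.005, 0.10); HIGH:
  U(0.30, 0.70), bracketing a high-group mean near 0.57 while keeping
  the truth continuous so recoverability correlations are well-defined).
  Onset draws whose objective latency exceeds 25 min are redrawn so the
  subjective window stays inside the onset segment.
* **Signals**: rendered only for the windows the pipeline scores (the
  onset segment and REM bouts) to keep runtimes at desk scale. Occipital
  channels are 1/f noise with 10 Hz bursts covering a known fraction of
  3-s micro-epochs (amplitude set per channel to a fixed multiple,
  default 4, of the channel's own alpha-band envelope median — the
  envelope SNR is therefore known by construction); frontal channels
  carry biphasic K-complex templates (−70/+45 µV, 1 s) at known times;
  the chin-EMG channel is low-amplitude noise with amplitude bursts at
  the scheduled arousals, which also add a 10 Hz shift burst to the
  occipital leads. True alpha density per subject is drawn from
  U(0, 0.08) (LOW) or U(0.05, 0.35) (HIGH), bracketing reported subgroup
  means near 2.6% and 16.5%; true A-REMd from U(0.1, 0.7) around a mean
  near 0.4.
* **Diaries** follow the misperception model:
  `SL_subj = SL_obj exp(6 alpha + e1)` (multiplicative, matching the
  ratio form and heavy right skew of SLm) and
  `TST_subj = TST_obj (132.67 - 56.04 AREMd - 178.48 alpha + e2)/100`
  (linear on the TSTm percentage scale, using the reported regression
  coefficients as the generating truth so the pipeline's estimator is
  well-specified). Noise defaults: e1 ~ N(0, 0.2) on the log scale,
  e2 ~ N(0, 10) in TSTm percentage points; the recovery experiments use
  e2 ~ N(0, 17), the residual scale implied by a response SD of 26.3
  with 59% of variance explained.
* **The 8/8 split is guaranteed by construction**: LOW subjective
  latencies are capped at `SL_obj + 8` min and HIGH ones floored at
  `SL_obj + 12` min. Under the defaults the LOW cap rarely binds; the
  HIGH floor binds for subjects whose objective latency is short (a
  6-fold overestimate of a 2-min latency is still under 10 min), which
  compresses the high group's discrepancies toward 12 min. The split,
  not the discrepancy distribution, is the design target.

What the generator does **not** emulate: physiologically realistic
full-night EEG (no spindles, slow waves, artifacts, or topography),
inter-night variability, scorer disagreement, or any dependence of diary
error on time-of-night beyond the two modeled indices. Passing tests
therefore demonstrate that the estimators recover the quantities they
define under the stated noise model — not that those quantities are
unbiased on clinical recordings.

## Numerical choices and degenerate inputs

* Filters: 4th-order Butterworth, applied forwards and backwards
  (zero-phase), band edges clipped below Nyquist; envelopes by the FFT
  analytic-signal method; 0.5-s moving-average smoothing for the arousal
  criteria.
* Sampling rate must be at least 100 Hz so the alpha band and >16 Hz
  shift content are resolvable; the generator default is 128 Hz.
* All-wake hypnograms: SL undefined (`NA`), TST 0, warning — never a
  sentinel value. Subjective windows shorter than two epochs yield a
  missing transition matrix with a warning. Constant samples skip the
  normality gate. `SL_obj = 0` excludes a subject from SLm (warning,
  counted).
* Exact-test cutoffs: Mann–Whitney enumeration up to `min(n) = 8` (and
  total n 20), making 8-per-group comparisons exact; Spearman
  permutation null up to n = 8.
* Report precision: two decimals in tables; machine-readable outputs at
  full precision. Reruns with an identical configuration produce
  byte-identical `subjects.csv`, `stats.json`, `transitions.csv` and
  `manifest.json` (the manifest carries a hash of the configuration).

## Problem sizes used in the test suite

The suite validates estimator recovery at sizes chosen to finish in
minutes on one CPU: Markov MLE consistency at 10^4 and 10^5 transitions
(max absolute error bounds 0.05 and 0.02); rank statistics exhaustively
for all tie-free arrangements with n1 = n2 <= 6 plus 1000 random small
samples against enumeration oracles; alpha-density recovery at ten burst
coverages on 6-min windows; stepwise recovery on 200 cohorts of n = 200;
detector ground-truth tracking on a 12-subject signal cohort and a
50-subject hypnogram cohort (transition estimates are correlated with
the generator over the full onset segment the chain governs — the
subjective window can contain too few N1 visits for a per-subject
estimate to rank stably); and the 16-subject end-to-end demo run twice
for byte identity.

## Known limitations

* The detectors are rule-based stand-ins, tuned to be faithful to their
  stated scoring rules on synthetic signals; their agreement with human
  scorers on real PSG is untested here.
* Alpha-density recovery assumes at least ~10% of micro-epochs are
  alpha-free in the scored window (two-pass baseline) and envelope SNR
  of about 3 or better.
* Single night per subject; no multi-night averaging, no covariate
  adjustment (e.g. medication), no multiple-testing correction — the
  statistics layer mirrors a small-sample exploratory design.
* The Markov analysis is first-order and restricted to the sleep-onset
  window by design; whole-night dynamics are out of scope.
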