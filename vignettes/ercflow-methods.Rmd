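---
title: "Event-related causality between STN and cortical speech areas: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-related causality: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ercflow)
```

# The scientific problem

During overt reading, the subthalamic nucleus (STN) exchanges information
with cortical speech areas — the superior temporal gyrus (STG, auditory),
the precentral gyrus (PreCG, motor), and the postcentral gyrus (PoCG,
somatosensory). Intraoperative recordings during DBS surgery capture local
field potentials from STN macroelectrode sites simultaneously with cortical
strip electrodes while the patient reads aloud words and pronounceable
pseudowords. `ercflow` estimates the *direction*, *intensity*, and *time
course* of high-gamma (60–180 Hz) activity propagation between these sites,
and tests when propagation increases relative to a pre-stimulus baseline —
event-related causality (ERC).

# Model and estimator

## MVAR processes

All channels are jointly modelled as a multivariate autoregressive (MVAR)
process

$$x(t) = \sum_{j=1}^{p} B_j\, x(t-j) + e(t), \qquad e(t) \sim N(0, \Sigma_e).$$

Some presentations write the recursion with a leading minus and matrices
$A_j$; the package standardizes on the plus convention ($B_j = -A_j$)
in the generator, the estimator and the test oracles alike, so that a single
sign convention flows through every module.

Granger causality lives in the off-diagonal coefficients: channel $l$
influences channel $k$ if past values of $l$ improve the prediction of $k$.

## Short-time multi-trial estimation

Task dynamics are non-stationary, so the MVAR model is fitted in short
sliding windows — 140 ms long, shifted by 5.6 ms — treating the repeated
trials as realizations of the same local process. At the analysis rate of
1250 Hz these are exactly 175 samples stepped by 7; the rate was chosen
precisely so that the published window geometry is an integer number of
samples (the original acquisition rate, 30 kHz, is far above what a
60–180 Hz analysis needs; `resample_recording()` provides the anti-aliased
path down).

Within each window, lag covariances are averaged across trials (per-trial
mean removed) and the Yule–Walker equations solved for $B_1,\dots,B_p$ and
$\Sigma_e$. Two numerical choices matter:

* **Unbiased lag normalization** (dividing lag-$j$ covariances by $N_s-j$):
  at 175-sample windows the biased variant tapers coefficients enough to
  distort model-order selection.
* **A relative ridge** ($10^{-8}$ of mean channel power on the Toeplitz
  diagonal, $10^{-10}$ on the spectral matrix): forward–backward FIR
  filtering suppresses out-of-band power by >100 dB, so the covariance
  structure is legitimately near-singular. The ridge is orders of magnitude
  below estimation noise and only prevents numerically meaningless solves.

The data-sufficiency rule $K(p+1)/(N_s n_t) < 0.1$ is checked before every
fit; the pipeline refuses to run configurations that violate it, citing the
computed ratio.

Two further small-sample safeguards act inside the sliding loop: the fitted
innovation covariance's spectrum is clamped to a tiny positive floor (noisy
fits can return a marginally indefinite matrix), and estimated models whose
companion spectral radius reaches the unit circle are shrunk radially
($B_j \to c^j B_j$) to radius 0.995 before spectral evaluation. Without the
latter, a single window fit with a pole on the unit circle concentrates
unbounded transfer-function mass at one frequency and hogs the SdDTF
normalization for the entire window.

## Order selection

A single global order per session is chosen by AIC on a stratified sample of
windows, $AIC(p) = N\log\det\hat\Sigma_e(p) + 2pK^2$, where
$\hat\Sigma_e(p)$ is the covariance of one-step-ahead residuals evaluated on
a conditioning range shared by all candidate orders ($t > \max p$). Both
details are essential, and were arrived at after the naive variants failed:
the Yule–Walker identity covariance improves by roughly twice the AIC
penalty per spurious order, and scoring each candidate on its own
$(N_s-p)$-sample range injects a random walk of several AIC points per order
step into the comparison.

## SdDTF

For each fitted window, the transfer matrix
$H(f) = \left(I - \sum_j B_j e^{-2\pi i f j / f_s}\right)^{-1}$
captures *directed* relationships and the partial coherence
$c_{kl}(f) = M_{kl}/\sqrt{M_{kk} M_{ll}}$ with $M = S^{-1}$,
$S = H \Sigma_e H^*$, captures *direct* (non-mediated) relationships. The
short-time direct directed transfer function combines them:

$$z_{kl}(f,t) = \frac{|h_{kl}(f,t)\,c_{kl}(f,t)|}
 {\sqrt{\sum_f \sum_{k\neq l} |h_{kl}(f,t)\, c_{kl}(f,t)|^2}}.$$

The normalization family is a deliberate resolution of an ambiguity: the sum
runs over the 60–180 Hz analysis band and all *ordered off-diagonal* pairs,
*within each window*. This keeps windows comparable over time, keeps the
diagonal self-flows out of the unit budget, and gives the two properties the
method advertises — $z \in [0,1]$ everywhere, and $\sum z^2 = 1$ per window.
A fully independent set of channels has all numerators (and hence the
denominator) exactly zero; the package returns zero flow for that case
rather than erroring, because "no direct causal relationship" is the
meaningful value of $z$ there.

The frequency grid is 60–180 Hz in 4 Hz steps (31 bins); the band is fixed
by the high-gamma hypothesis, the step is a resolution choice.

# Preprocessing

Epochs are cut half-open with $t=0$ at the alignment event: cue-aligned
520 ms baselines (inside the inter-trial interval) and speech-onset-aligned
1 s response epochs. Artifact rejection replaces visual inspection with a
reproducible rule — a trial is dropped when any channel's peak deviation
exceeds 8 robust SDs (MAD) — and reports counts and percentages. The common
average reference is computed over all retained channels *after* rejection;
band-pass filtering (windowed-sinc FIR, ≥40 dB stopband one 10 Hz transition
outside 60–180 Hz, applied forward–backward for zero phase) runs on epochs
padded by one filter length and trimmed back, so edge effects never reach
the analysis windows. Optional narrow notches at line harmonics exist behind
a flag but are off by default for synthetic data; whether the original
analysis notched inside its own passband is not determinable and the package
asserts neither behaviour.

One ordering decision deserves emphasis: the activation screen runs on
*unreferenced* epochs. The common average contains the task-evoked power of
the active channels, so referencing *before* screening leaks activation into
quiet channels — and if the screen then selects the entire reference group,
the referenced data are exactly rank-deficient and the MVAR solve is
singular. Screening first avoids both problems.

# Statistics

## Channel screen

Per channel and frequency, each post-stimulus time point's log power
(Hann STFT, 100 ms windows, ~10 ms step) is compared to the same trial's
mean baseline log power with a paired two-sided t statistic; a channel is
eligible for ERC only if some point in the band shows a significant
*increase*. Spectrogram power is chi-square-like, and its skewness inflates
the tabulated t distribution exactly in the far tail where a ~400-point
family is decided — in simulation, t + within-channel FDR selected ~20% of
null channels at $\alpha = 0.05$. The channel-level decision is therefore
calibrated by a bootstrap-t reference for the family maximum (500 trial
resamples of the mean-centred differences, private fixed RNG stream), which
is second-order accurate under skewness and restores the advertised
false-selection rate. A relative noise floor ($10^{-4}$ of mean baseline
power) bounds log outliers.

## Session-level ERC

Smoothed ($9 \times 5$ point 2D moving average, ≈50 ms × 20 Hz; uniform
kernels shrink at edges rather than inventing padding) task fields are
compared to baseline per directed pair. The inference unit is the **trial
group**: trials are split round-robin into $G = 5$ groups, the SdDTF is
estimated separately per group, and each task point minus the group's own
mean baseline yields one replicate difference, tested against zero with a
one-sample t. This replaces referencing task points to the pooled
across-window baseline distribution, which is *not* a valid reference here:
adjacent 140 ms windows shifted by 5.6 ms share 96% of their samples, so a
520 ms baseline contains only ~3 effectively independent windows, and the
across-window spread cannot see the per-epoch estimation-noise level (null
masked fractions measured ~0.077 at $\alpha = 0.05$). Replicate variance is
pooled over time per (pair, frequency) — replicate noise is stationary
across the epoch while true effects are sparse in time — with degrees of
freedom credited only for effectively independent windows
($(G-1) \times n_w \cdot \mathrm{step} / N_s$). Benjamini–Hochberg FDR runs
over each pair's (frequency, time) family at $\alpha = 0.05$, and only
increases enter the mask: flow decreases are deliberately not interpreted.

## Group level and contrasts

Sessions are the unit of group analysis (each session records a distinct STN
site set). Session results are pooled into directed region-pair classes
(e.g. STG→STN): per session, the smoothed flow change is averaged over the
class's *session-significant* channel pairs and the band, giving one time
course per session. Carrying only significant session-level flows to the
group stage mirrors the method's intent and avoids diluting a single coupled
site pair by a class's full pair count; a class absent from a session's
masks simply contributes no course for that session. Per
class and time point, a two-sided t test with the standard deviation of the
estimated mean difference as the normalizing standard error (across-session
SD/√n; a bootstrap was the other reading of that construction and is noted
as an open alternative), BH-FDR across the class's time points, masks only
positive means. Classes present in fewer than two sessions are excluded with
a warning. Word–pseudoword contrasts pair the two conditions' class courses
session by session (paired t, BH, signed mask); condition courses use pair
selection from the *pooled* result so that which sites enter a class is
condition-neutral and the contrast unbiased. Because an effect confined to a
known pre-speech window spreads its evidence over many time points, the
contrast additionally reports window-level tests: the course difference
averaged over each named preset interval, one paired t per class and window,
BH across classes. Integrated flow graphs average significant increases over
the same named intervals: `pre_speech_burst` (−450 to −400 ms),
`lexical_contrast` (−208 to −117 ms), `flow_integration` (−500 to −300 ms).

# The synthetic cohort: what it emulates, and what it does not

The generator exists so that every stage can be validated against known
ground truth. `build_default_cohort()` produces 10 sessions across four
subjects (4/3/2/1), 60 alternating word/pseudoword trials each — 600 trials
in total — with three STN sites plus cortical contacts per session.

* **Task timing.** A 250 ms cue, a uniform 500–1000 ms ISI, then the
  stimulus; reading latency and C1/V/C2 articulation durations are drawn
  from truncated normals with means 736/818 ms (word/pseudoword latency),
  93/105, 217/203, 170/187 ms (C1, V, C2). Published dispersions are
  standard errors; trial-level SDs are back-computed as SEM × √30, with 30
  the per-condition trial count of a session. The pooled-trial alternative
  (SEM × √296, SD ≈ 585 ms) makes the truncated-normal mean drift far above
  the published means and renders the paradigm's latency contrast
  undetectable at any plausible power — it is not a usable reading.
* **Background dynamics.** Each channel is an AR(2) resonance near 120 Hz
  (pole radius 0.85) — a band-limited high-gamma carrier. The spectral shape
  of real task-evoked high-gamma is not characterized beyond its band
  limits; this carrier is a modelling choice, not a data fact.
* **Task-evoked activation.** Innovation SD doubles (+6 dB power) from
  stimulus onset to 500 ms after speech onset on activated channels, with
  50 ms cosine ramps. Because the SdDTF is self-normalized per window, a
  pure gain change induces no spurious flow — activation and propagation are
  independently controlled.
* **Ground-truth couplings** are extra cross-channel lag coefficients
  switched on in trial-locked windows (10 ms cosine taper): an STG→STN
  burst at (−450, −400) ms in both conditions (gain 0.25); a
  lexicality-modulated STG→STN flow at (−208, −117) ms (word 0.30 >
  pseudoword 0.15); reciprocal STN↔PoCG at (−300, +400) ms (0.15 each way);
  PreCG→STN at (−350, −150) ms (0.20). Per-session gains jitter uniformly
  within ±10%. Gains were bounded a priori by two constraints: a reciprocal
  lag-2 pair on an AR(2) carrier of pole radius $r$ is stable only below
  $1 - r^2 = 0.2775$, and a driven channel's amplitude (inflated by roughly
  $\sqrt{1 + (g/(1-r))^2}$ through the resonance) must stay clearly under
  the 8-robust-SD artifact threshold on clean data. Couplings target
  distinct STN sites so no single channel accumulates variance.
* **Two non-activated cortical contacts** per session are screened out
  downstream, which also keeps the modelled subset a strict subset of the
  common-average reference group.

What the generator does *not* emulate: 1/f broadband structure, line noise,
movement artifacts, electrode impedance drift, cross-frequency coupling,
behavioural error trials, or any disease physiology. A green test
establishes that the estimator and statistics recover the stated MVAR-world
ground truth at the stated sample sizes — not that they would behave
identically on patient recordings.

# Degenerate inputs and tie-breaks

* Fully independent channels → zero flow, not an error.
* All Wilcoxon differences zero → statistic 0, $p = 1$, degenerate flag;
  tied |differences| are handled by an exact dynamic program over doubled
  midranks (verified against exhaustive sign-flip enumeration to $n = 8$).
* The SEM convention divides the *population* SD (denominator $n$) by
  $\sqrt n$ — the convention that reproduces the published descriptives
  (e.g. ages 68, 82, 71, 60 → 70.25 ± 3.94; the sample-SD convention gives
  4.55).
* Flow-diagram trimming drops `floor(0.15 × n_nonzero)` smallest edges.
* Out-of-bounds trials are flagged with a reason, never silently dropped.

# Known limitations

* The replicate-group t (df = 4 by default, moderated by time-pooled
  variance) is conservative for very short effects at low trial counts;
  sustained weak flows need either more trials or more groups.
* The bootstrap-t screen decision is channel-level; per-point q-values
  within selected channels are not individually calibrated.
* CAR plus volume-conduction-free simulation means the generator cannot
  probe zero-lag mixing artifacts that real referenced recordings face.
* A single AIC order serves all windows and condition subsets of a session;
  window-wise orders would fragment the sufficiency budget.
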