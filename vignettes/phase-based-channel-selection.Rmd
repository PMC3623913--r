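---
title: "Phase-based channel selection for P300 spellers: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-based channel selection for P300 spellers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A P300 matrix speller flashes the six rows and six columns of a 6x6
character grid while the user attends one cell. The attended row and column
(2 of the 12 stimuli per repetition) elicit a P300 response; summing
classifier scores over repetitions and intersecting the winning row and
column decodes the character. Recognition accuracy depends strongly on
*which* electrodes feed the classifier, and the informative montage is
subject-specific. This package ranks channels from a user's own recordings
using only the *phase* of the EEG, and evaluates the ranking with the full
decoding loop.

## Phase statistics

All statistics are computed on the instantaneous phase
`phi(t) = Arg(x(t) + i H(x)(t))` of the band-passed (0.1-40 Hz), 200 Hz
signal, where `H` is the Hilbert transform. For channels `x`, `y` and `n`
trials, per time point:

* **PLV** `= |1/n * sum_k exp(i(phi_x - phi_y))|` — consistency of the
  phase *difference*. High PLV means a constant lag: the two channels
  mirror one (homologous) source.
* **ITC** `= |1/n * sum_k exp(i phi_x)|` — single-channel phase
  concentration, the classic signature of stimulus phase reset.
* **PCV** `= |1/n * sum_k exp(i(phi_x + phi_y))|` — the two-channel
  extension of ITC through the joint phase `phi_x + phi_y`. The *sum*
  makes PCV blind to a fixed inter-channel lag (it only rotates the mean
  direction) but demanding about across-trial concentration of both
  phases: it is high exactly when the pair is phase-synchronized to the
  task.
* **PLCV** `= PCV * (1 - PLV)` — high for *heterologous* pairs that are
  jointly task-synchronized. The multiplicative form makes
  `PLCV(x, x) = 0` identically, since `PLV(x, x) = 1`.
* **TE** `= PLCV_target - PLCV_nontarget`, each term computed over its own
  trial set — the pairwise relevance signal. `TE(x, x) = 0` for any
  channel paired with itself.

PCV and the PLCV combination admit more than one plausible reading; the
forms above were chosen because (a) the joint-phase sum realizes the
intended contrast — PLV asks "same source?", PCV asks "task-related?" —
and (b) only the product form nulls the self-pair exactly, a property the
target effect must have. The code computes all circular sums on unit
complex numbers, never on raw angles, so wrap-around is never an issue.

## The ranking recursion (PLCV-RFE)

TE varies over the 0-700 ms response window, so the scalar similarity of a
pair is `S[x, y] = max_t TE_{x,y}(t)` over a configurable window (default
the full window; the package does not exclude an early post-stimulus
interval, as no such exclusion is established). Starting from all `n`
channels:

1. build a single-linkage hierarchy over the surviving channels treating
   `S` as a distance, and cut it into `k - 1` groups; exactly one group
   has two members and it is the globally least-similar (most redundant)
   couple — the implementation also locates that couple by direct argmin,
   asserts agreement with the tree cut in its step log, and breaks exact
   ties lexicographically;
2. compute for both members the task-relativity value
   `TRV_x = mean of S[x, y] over surviving partners y` and eliminate the
   lower-TRV member (ties: the lower montage index), prepending it to the
   rank list;
3. repeat until one channel remains; it ranks first.

An earlier-eliminated channel ranks lower. Because the pairwise TE of two
channels does not depend on which other channels survive, the similarity
matrix is computed once and subset as channels are eliminated;
`recompute_similarity = TRUE` recomputes it from phases each iteration and
is verified in the tests to give identical results. TRV is recomputed
every iteration since its survivor average shrinks with `k`.

Per-run rank lists are aggregated across sessions or subjects by scoring
rank positions, standardizing to z-scores within each list, and averaging
(`aggregate_channel_weights()`).

## Decoding and evaluation

`flda_train()` fits Fisher's linear discriminant on single-trial feature
vectors: the 0.7 s response at 20 Hz (two-stage decimation 1000 -> 200 ->
20 Hz), 14 samples per channel, concatenated in montage order. The pooled
within-class covariance gets an additive ridge `1e-6 * trace/d`: with up
to 448 features and a few thousand trials the covariance is
near-singular, and the ridge is small enough to leave well-conditioned
problems untouched (the tests require cosine >= 0.999 against the
unregularized closed form). Class imbalance (1:5) is left as-is, standard
for this paradigm; trials are not averaged before fitting.

`cre_curve()` retrains the FLDA for every top-`n` channel subset of a rank
list and every repetition count, decodes each test block (ties in the
row/column argmax go to the lowest code index) and reports the character
recognition error (CRE). The evaluation protocol is first-half train /
second-half test over blocks, configurable through `split`. `ocs()`
returns the *optimal channel subset*: the smallest subset size attaining
the row minimum of the CRE — least error with least channels.

## What the simulator emulates

`simulate_session()` generates the complete paradigm — 2.5 s blank, then
12 intensifications of 100 ms + 75 ms blank per repetition, 15 repetitions
per block, 80 blocks by default (2,400 target / 12,000 non-target trials)
— and continuous EEG under the oscillatory account of ERP generation:

* each source is a sinusoid with Brownian phase drift (1.5 rad/sqrt(s)),
  drawn from 2-7 Hz; pure fixed-frequency sinusoids would make PLV
  degenerate and would let onset times alias into phase structure. The
  delta/theta range was chosen because the P300 is a low-frequency
  component and the 20 Hz classification chain (anti-alias cutoff 8 Hz)
  must be able to see the reset sources;
* the `channels x sources` mixing matrix defaults to identity (one private
  source per channel); rows sharing a source define homologous pairs with
  PLV near 1;
* at each *target* stimulus, sources feeding the `relevant_channels` have
  their phase redrawn from von Mises(`mu_reset = 0`, `kappa = 5` by
  default) 300 ms after onset, blended over a 50 ms raised-cosine ramp to
  avoid filter-ringing discontinuities, then free-running again;
* each channel adds 1/f background (SD 2 uV) and white sensor noise
  (SD 2 uV) against a 5 uV oscillation amplitude — a deliberately
  conservative single-trial SNR for scalp EEG;
* `evoked_amplitude > 0` switches in the competing additive model: a
  fixed-latency, fixed-polarity Gaussian bump on the relevant channels.

All randomness flows from one seed through a single R stream with a fixed
draw order (characters, schedule, oscillators, resets, noise), so sessions
are bit-reproducible and the caller's RNG state is untouched.

**What it does not emulate.** No volume-conduction head model (mixing is
chosen, not physical), no ocular/muscle artifacts, no inter-subject
variability in latency or topography, and reset persistence means
non-target trials shortly after a target inherit some phase alignment —
as real resets would — which slightly dilutes the target/non-target
contrast. Passing tests on these sessions show the algorithm recovers
planted phase structure at realistic SNR; they do not certify performance
on recorded EEG.

## Numerical choices

* **Zero-phase filtering.** All filters run forward-backward with
  odd-reflection end padding: group delay would bias phase estimates. The
  band-pass is a 2nd-order Butterworth high-pass (0.1 Hz) cascaded with a
  6th-order low-pass (40 Hz) — the cascade keeps the extreme low edge
  numerically stable. Decimation uses the standard 8th-order Chebyshev-I
  anti-alias filter at 80% of the target Nyquist, renormalized to exact
  unit DC gain.
* **Hilbert edges.** The analytic signal is computed on epochs padded by
  ±1 s and cropped back to 0-700 ms, so FFT edge artifacts never reach
  the statistics. Whether phase should be computed on isolated epochs or
  on continuous data is not settled; padding approximates the continuous
  choice.
* **Degenerate inputs.** A single surviving channel is prepended without
  clustering; `kappa = 0` resets draw uniform phase (no concentration,
  verified by a null test); all-equal decoding scores fall back to the
  lowest row/column.

## Problem sizes used by the test suite

Analytic identities run on small random tensors (20 trials x 5 channels x
50 samples). Stochastic suites use desk-scale sessions chosen once:
channel-recovery runs 50 seeds of 16 channels / 4 reset channels /
kappa = 5 with 6 blocks at 200 Hz (the phase-analysis rate, so decimation
is a no-op); redundancy and ITC-gap suites use 2-4 blocks with 4-8
channels; the paradigm-count check simulates the full 80-block protocol at
200 Hz. At these sizes the whole suite completes in a few minutes on one
CPU while leaving the statistical margins wide (the recovery criterion
asks for >= 80% success; observed rates are well above).

## Known limitations

* The TRV definition (survivor-mean of S) is one defensible reading of a
  quantity the method needs; alternatives incorporating PCV terms directly
  would change tie behavior in low-contrast regimes.
* EDF support covers continuous, equal-rate signals only, with 16-bit
  quantization; the native RDS container is the lossless path.
* FLDA is the only classifier; the package deliberately does not implement
  SWLDA/SVM baselines.
* The CRE curve retrains one FLDA per subset size; for 32 channels and 15
  repetition counts this is 32 fits per evaluation, which is fast, but no
  incremental refitting is attempted.
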