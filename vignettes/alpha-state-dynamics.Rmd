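---
title: "Alpha-state dynamics: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-state dynamics: model, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphastates)
```

## The model

The EEG alpha rhythm (8–13 Hz) is bistable: its amplitude alternates
erratically between a high and a low mode. `alphastates` treats that
alternation as a symbolic process on 1-second epochs. Each epoch's mean
alpha-band power $P_t$ is compared with an individualized threshold
$\theta$ and labeled

$$s_t = \mathbf{1}\{P_t > \theta\} \in \{0, 1\},$$

with 1 the high alpha state. The binary sequence $s_{1:T}$ is then
summarized by three families of parameters:

* **Fractional occupancy** — the fraction of epochs spent high,
  $\mathrm{FO} = \frac{1}{T}\sum_t s_t$.
* **Dwell times** — lengths of maximal runs in one state, summarized by
  mean, median, mode, a variance measure and a tail-weight statistic.
* **Transition probabilities** — the sequence is modeled as a two-state
  Markov chain with matrix
  $$P = \begin{pmatrix} 1 - p_{LH} & p_{LH} \\ p_{HL} & 1 - p_{HL} \end{pmatrix},$$
  estimated by maximum likelihood. Because the states are observed (the
  "emission" from state to symbol is the identity), the MLE is exact pair
  counting followed by row normalization; the test suite asserts
  equivalence to a one-step identity-emission Baum–Welch update. The
  stationary high-state probability has the closed form
  $\pi_H = p_{LH} / (p_{LH} + p_{HL})$, which links the occupancy and
  transition summaries and is used as an internal consistency check.

At the behavioral level, each session carries cold-pressor pain blocks of
six VAS ratings (0–10, one every 30 s over 3 min). A session's pain level
is the block mean; its change score subtracts the session-1 pre-training
baseline mean. State parameters are tested for session effects with a
Friedman test (df = sessions − 1) and correlated with pain change by
Pearson correlation within each group.

## Thresholding

The threshold is a percentage (30/50/70 by default, 30 being the primary
setting) of the participant's *maximum alpha power*, derived from the
session-1 resting eyes-open recording and reused for all of that
participant's sessions. "Maximum" is deliberately not the sample maximum:
a single transient can then set the scale. It is read here as the Tukey
upper fence $Q_3 + 1.5\,\mathrm{IQR}$ of the resting per-epoch power
(quantiles by linear interpolation). A literal $1.5 \times \mathrm{IQR}$
variant is available (`max_alpha_power(..., method = "literal")`) but it
is a spread rather than a power level and can fall below the median, so
the fence is the default. Ties at the threshold go to the low state
(strictly-above labeling); ties have probability zero for continuous
power, so the choice is a determinism device, not a modeling one.

Epochs flagged as artifacts are dropped *before* symbolization, and the
state sequence is the concatenation of retained epochs. A gap-aware
alternative (breaking dwell runs at gaps) is deliberately not the default:
with the synthetic generator's low rejection rates it changes nothing, and
on real data it would require a per-dataset decision about gap lengths.

## Preprocessing conventions

* Downsampling 1000 → 250 Hz: zero-phase Butterworth low-pass of order 6
  with cutoff at 80% of the target Nyquist, then decimation. A sub-Nyquist
  sinusoid's amplitude survives within 1% (tested).
* Epochs: 1-s, non-overlapping, trailing partial epoch discarded.
* Artifact criterion: peak |amplitude| > 100 µV on any channel flags the
  epoch; a warning is raised when more than 10% of epochs are flagged,
  replacing a hard cap on discarded data. This deterministic criterion
  stands in for manual visual inspection; ICA-based ocular/muscle cleaning
  is out of scope and the generator plants no such components.
* Band power: rectangular-window periodogram per epoch, scaled so the
  power values sum to the time-domain mean square (Parseval; tested to
  1e-6 relative). Alpha power is the *mean* over the bins lying inside
  [8, 13] Hz with both edges inclusive (six 1-Hz bins for 1-s epochs at
  250 Hz), averaged over channels AF3 and AF4. Window function and band
  edges are configurable; these defaults are the simplest reading of a
  Fourier-based band average.

## Dwell-time statistics

Boundary runs (the first and last run, truncated by the recording edges)
are *included* and flagged; excluding them would bias short recordings
toward longer apparent dwells, and a censored mode is available
(`extract_dwells(..., censor_boundary = TRUE)`) — the geometric-dwell test
uses it, since only interior dwells are exactly geometric.

Two of the printed summary statistics have no unique formula, so both are
implemented as named, configurable statistics and every output records
which definition produced them:

* **Variance (%)** — rendered as the coefficient of variation,
  $100 \cdot \mathrm{sd}/\mathrm{mean}$. A plain variance of small integer
  dwells cannot be a percentage; the CV can. A single dwell yields 0 (no
  observed variability).
* **Tail weight** — default: the maximum-likelihood power-law exponent of
  the dwell distribution above its median (discrete Hill-type estimator
  with the standard $-\tfrac12$ continuity correction,
  $\hat\alpha = 1 + n \big/ \sum_i \ln \frac{x_i}{x_{\min} - 1/2}$).
  A planted discrete power law with exponent 2.5 is recovered within ±0.2
  (tested). Alternatives: mean/median ratio and excess kurtosis.
* **Mode** — smallest duration among the most frequent (deterministic
  tie-break).

In the cohort table, dwell statistics are computed on the *high-state*
dwells of each participant-session (the high state is the training
target); group summaries then average across participants. Sequences
that never visit the high state yield `NA` dwell statistics rather than
an error.

## The feedback dial

The real-time loop is re-implemented offline for simulation and audit: a
10-s sliding window is band-pass filtered at 8–13 Hz (zero-phase
Butterworth, order 4 forward–backward, odd-reflection padding of 1 s to
absorb edge transients), and the feedback power is computed on the last
2 s of the filtered window. Power here is the time-domain mean square of
the band-limited segment — by Parseval this equals the sum of its
periodogram, so a pure in-band sinusoid of amplitude $a$ reads $a^2/2$
(tested within 5%, and within 1% in practice). A band-bin *mean* (the
offline epoch convention) was considered and rejected for the online path:
it divides by the number of bins, which depends on the window length, and
would break the sinusoid calibration property. Calibration maps the 2nd
and 98th percentile of resting alpha power (linear interpolation) to dial
0 and 10, with clipping; calibration should be computed with the same
power definition as the loop it calibrates. The update cadence is not
specified by the protocol being emulated; the default 1-s hop matches the
analysis epoch grain.

## The synthetic cohort generator

No raw recordings are distributed with the study this package emulates,
so the generator is a first-class module, not a test fixture. It
emulates:

* state dynamics as a two-state Markov chain at 1-s resolution (the
  analysis grain), with per-group starting probabilities and linear
  per-session drift ("learning") clipped to [0, 1];
* the signal as a phase-continuous 10-Hz oscillator whose amplitude is
  20 µV (high state) or 5 µV (low state), plus per-channel 1/f-shaped
  ("pink") Gaussian noise (SD 2 µV) and white noise (SD 1 µV) at
  1,000 Hz on channels AF3/AF4;
* the design: two groups, 4 participants each, 5 sessions, 2-min resting
  and 10-min NFB recordings;
* behavior: six VAS ratings per pre/post cold-pressor block whose session
  mean follows
  $\mu_s = \text{baseline} - \beta\,(\mathrm{FO}_s - \mathrm{FO}_1)$ plus
  rating noise, clipped to [0, 10]. Defaults: baseline 7, slope
  $\beta = 5$ VAS units per unit occupancy gain for patients and 0 for
  healthy participants, rating SD 0.5.

Group dynamics defaults anchor on the reference cohort's session-1
estimates (healthy: $p_{LH} = 0.53$, $p_{HL} = 0.25$, no drift; patients:
$p_{LH} = 0.37$, $p_{HL} = 0.22$ with $p_{HL}$ drifting −0.04/session,
the direction of the reported patient trend). Drift magnitudes, the pain
slope and noise levels are free parameters of the generator, chosen once
as plausible for this design — no quantitative within-session trajectory
or effect size is on record to match.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: within-state amplitude variability (real
alpha fluctuates inside each mode; here each state has a fixed amplitude,
so epoch power distributions are much cleaner than real ones, and high
thresholds like 70% can classify every epoch low), eye-blink/EMG
artifacts beyond optional amplitude spikes, volume conduction and
multi-source mixing, non-stationarity within a session, and any coupling
between pain and the EEG other than the planted occupancy term.

## Numerical and degenerate-case conventions

* Quantiles everywhere use linear interpolation (R type 7).
* An unvisited origin state leaves its transition row `NaN` with a
  warning (error in strict mode); no smoothing is applied by default so
  absorbing behavior stays visible, with optional additive smoothing.
* A fully session-constant parameter matrix carries no rank information;
  the Friedman wrapper returns $\chi^2 = 0$, $p = 1$ instead of the
  0/0 the tie-corrected formula would produce.
* Zero variance across sessions in the normalized mean alpha yields
  all-zero scores with a warning; zero variance in a correlation input
  yields `NA` with a warning.
* Pipeline correlations pool all (participant, session) pairs within a
  group. The within-participant dependence this ignores is a known
  limitation of the emulated analysis, kept for comparability; the
  building blocks accept any grouping for alternatives.
* The session pain level defaults to the *pre*-session cold-pressor
  block (configurable: pre/post/mean); which block the emulated analysis
  used is not on record, and the pre block keeps the pain measurement
  closest in time to the state parameters of the same session.
* Mean alpha power is normalized within participant across sessions
  (log → session mean → z-score), so group values straddle 0 with SD
  near 1; an across-epoch alternative is configurable.

## Problem sizes

The test suite and the acceptance script run at sizes chosen to make
sampling error negligible relative to the tolerances they assert:
stationary/closed-form checks are exact; transition recovery uses
$10^5$-epoch sequences (SE ≈ 0.003 on a probability of 0.5); the
end-to-end EEG pipeline check synthesizes $10^4$ epochs at 1,000 Hz
(occupancy SE ≈ 0.006 after accounting for chain autocorrelation);
property batteries use 20–100 seeded replicates. Pipeline unit tests use
deliberately small cohorts (minutes of signal at 250 Hz) since they check
wiring and determinism, not statistical power.

## Known limitations

The two-state model is a deliberate reduction: it ignores within-state
amplitude structure and any intrinsic threshold the bimodal amplitude
distribution might define (fitting a two-exponential amplitude mixture to
locate the modes' meeting point is an explicit non-goal here). The
chi-square approximation to the Friedman null is rough at 4 participants;
the tests bound its disagreement with a permutation oracle rather than
hide it. Pooled correlations overstate effective sample size for the same
reason they mirror the emulated analysis. EEG input is limited to
delimited text with a YAML sidecar; vendor formats are out of scope.
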