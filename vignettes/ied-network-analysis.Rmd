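---
title: "IED network analysis with phase transfer entropy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IED network analysis with phase transfer entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ezpte)
```

## The analysis in one paragraph

`ezpte` quantifies, electrode by electrode, how strongly cortical tissue
drives its neighbors during interictal epileptiform discharges (IEDs).
Ten-second ECoG epochs centered on IED markers are conditioned (common
average reference, 200 Hz, zero-phase 0.5–66.7 Hz FIR band-pass, 60 Hz
notch), decomposed with complex Morlet wavelets into narrow-band
instantaneous phase and power, and scanned with a 500-ms sliding window
across 3–65 Hz for the time–frequency point of maximal mean pairwise
phase transfer entropy ("point A"). A directed adjacency matrix of
pairwise PTE in the 500-ms analysis window centered on point A is
proportionally thresholded (lowest 70 % of off-diagonal weights
removed), seven node parameters are computed per electrode (BC, CC, LE,
OD, OS, ID, IS), averaged over epochs, multiplied by the epoch-averaged
maximum wavelet power in the same window and frequency band
(power-spectrum compensation), and compared across the epileptogenic
(EZ), margin (MZ) and normal (NZ) zones with two-tailed Mann–Whitney U
tests and in-sample logistic classification (cutoff 0.5).

## The estimator

Phases are quantized into uniform right-closed bins over (−π, π] and the
plug-in transfer entropy in bits is

TE(X→Y) = Σ p(y_{t+δ}, y_t, x_t) log₂[ p(y_{t+δ} | y_t, x_t) /
p(y_{t+δ} | y_t) ],

with the empirical joint histogram over the analysis window. The
directional index dPTE = TE_{XY}/(TE_{XY}+TE_{YX}) is 0.5 under
symmetry and defined as 0.5 when both directions vanish. A C++ kernel
computes all ordered pairs at once; y-marginals are shared across
sources.

**Prediction lag δ.** Default `max(1, round(fs/(4f)))` — a quarter cycle
of the analysis frequency — so the lag scales with the oscillation under
study. Configurable via `pteParams(delay =)`.

**Bin count.** `round(exp(0.626 + 0.4 ln(n − δ − 1)))` with `n` the
window sample count, capped at `floor(n/10)` so each bin can hold at
least ten samples. At the default 500-ms window (100 samples at 200 Hz)
the heuristic alone would give 12 bins; the occupancy cap lowers it
to 10. Without the cap the three-way histogram (B³ = 1728 cells for
fewer than 100 observations) is even sparser and the estimator even more
bias-dominated (see *Known limitations*).

**Window.** 500 ms wide, 100-ms step. Narrower windows starve the
histogram; much wider windows blur the IED and let high-amplitude
after-going slow waves bleed into the power compensation. Window centers
are restricted so the full window fits the epoch, which is also why
point-A candidates can never produce an out-of-range analysis window.

## Graph metrics

`W[i,j] = TE(i→j)` at the point-A frequency within the analysis window;
diagonal zero. The proportional threshold keeps off-diagonal entries
strictly above the `floor(q·m)`-th smallest (default q = 0.70, i.e. the
top 30 % by weight; 0.30 and 0.50 are supported as configuration
values). OD/ID count edges on the binarized matrix; OS/IS sum retained
weights. CC is Fagiolo's directed weighted clustering (weights rescaled
by the maximum retained weight; cube-root symmetrization; denominator
`2[d_tot(d_tot−1) − 2d_↔]`, zero when degenerate). LE is the mean
inverse shortest-path length inside the subgraph induced by each node's
in/out-neighborhood, and BC is Brandes betweenness, both on inverse
weight edge lengths, BC normalized by (N−1)(N−2). A binarized variant of
CC/LE is available (`nodeMetrics(weighted = FALSE)`); weighted is the
default. Shortest-path machinery is delegated to igraph; all three
nontrivial metrics are cross-checked in the test suite against
brute-force oracles (triangle enumeration, Floyd–Warshall, exhaustive
geodesic enumeration with proportional tie splitting) to 1e-9.

## Compensation and statistics

Averaging precedes compensation: for each electrode the seven parameters
and the maximum wavelet power at the point-A frequency are averaged over
all epochs, then each averaged parameter is multiplied by the averaged
power. The two operations do not commute; a regression test pins the
implemented order (parameters 2 and 4 with powers 1 and 3 give 3 × 2 = 6,
not mean(2·1, 4·3) = 7). Power is taken at the point-A frequency only —
phase and power are deliberately read from the same band — and left in
raw (µV)² units since compensation is within-recording.

The Mann–Whitney U test uses exact enumeration for combined n ≤ 12
without ties and the tie/continuity-corrected normal approximation
otherwise (this is `stats::wilcox.test`'s own switch, verified in tests
against full enumeration of all arrangements). No multiple-testing
correction is applied across the 21 parameter × pair tests by default,
mirroring the reference analysis; `compareZones(pAdjust = "BH")` appends
Benjamini–Hochberg-adjusted p-values. Logistic classification is fit and
evaluated
in-sample on the standardized compensated parameters; under complete
separation the fit is stabilized by a small ridge penalty (λ = 1e-3 on
standardized coefficients) and flagged.

## The synthetic generator

The generator emulates the study inputs: 10-s epochs at 200 Hz, 16–128
channels with an EZ/MZ/NZ partition, IED markers, EDF plus
`channel,zone` and `marker_seconds` CSV side-cars.

- **Background**: independent per-channel 1/f^α noise (default α = 1),
  FFT-shaped, unit variance.
- **IED template**: one (spike-wave) or several (polyspike-wave)
  biphasic sine-period transients (70 ms) followed by a 300-ms half-sine
  slow wave; demeaned; unit peak.
- **Coupled burst**: 500 ms of band-passed Gaussian noise (4 Hz wide,
  default carrier 21 Hz), Hann-windowed, at half the template's peak.
  The burst is *stochastic by design*: the phase of a deterministic
  sinusoid is fully predicted by its own past, so transfer entropy
  through it is structurally zero — detectable directed coupling
  requires phase innovations.
- **Coupling**: EZ channels emit template + burst at signal-to-noise 5
  (peak over background RMS); MZ receives a 0.7-gain copy at 15 ms lag;
  NZ a 0.1-gain copy at 30 ms lag. Markers carry 20-ms-SD jitter,
  clamped so epochs never overlap.

Desk-scale defaults are 16 channels (4 EZ / 4 MZ / 8 NZ) and 30 epochs —
deliberately smaller than a clinical grid (64–128 electrodes, 100
epochs) so a full pipeline run completes in about a minute; all sizes
scale through `simConfig()`. What the generator does **not** emulate:
electrode geometry and volume conduction, ictal events, high-frequency
oscillations (> 80 Hz), artifacts, non-stationary background, or
heterogeneous per-electrode SNR. A passing pipeline on this generator
demonstrates that the chain recovers planted directed coupling and zone
contrasts; it does not certify performance on clinical recordings.

## Numerical choices and conventions

- Zero-phase filtering is forward–backward (`filtfilt`) over symmetric
  FIR kernels; a symmetric test pulse's peak does not move. The mean is
  removed explicitly before band-passing, so DC rejection does not
  depend on the FIR stop-band depth at 0 Hz. Filter orders target ~1-Hz
  transitions and are capped by signal length.
- Rate standardization low-passes at 80 % of the target Nyquist before
  integer decimation (linear interpolation onto the new grid for
  non-integer ratios); upsampling is refused.
- An epoch needs a full symmetric margin: a marker whose window would
  exactly graze the recording edge is rejected, not clipped.
- Point-A ties break toward the earliest time, then the lowest
  frequency. The pre-normalization map maximum is kept in the `scale`
  slot so raw values can be reconstructed.
- Morlet wavelets use 7 fixed cycles (σ_t = 7/2πf), L1-normalized ×2 so
  a unit cosine yields unit-magnitude coefficients; samples within one
  wavelet half-length of an epoch edge are flagged per frequency.
- The EDF writer quantizes each channel to the full signed 16-bit range
  of its own amplitude maximum (round-trip error ≤ one digital step) and
  uses 1-s records; determinism extends to the file bytes for a fixed
  `SimConfig`.
- All randomness flows from explicit seeds (`SimConfig@seed`; the
  pipeline seed overrides it), so a run manifest suffices to reproduce a
  run bit-identically.

## Known limitations

**The raw mean-PTE map localizes IEDs in time, not narrow-band coupling
in frequency.** The plug-in estimator's bias on 100-sample windows
depends strongly on frequency (phase autocorrelation and histogram
occupancy vary with the quarter-cycle lag and the wavelet bandwidth),
and this bias landscape — not coupling — dominates the raw map's
across-frequency profile. Worse, at the carrier of a coherent
narrow-band burst the map value is typically *suppressed*: when the
shared component dominates the band, source and target phases become
nearly identical and smooth, the target's own past already predicts its
future, and the residual phase innovations (≲ 0.2 rad at in-band SNR
≥ 2) are smaller than a histogram bin. Controls with independent
(uncoupled) bursts reproduce the same flank elevation, confirming the
bias interpretation. Consequences, all visible in the test suite: point
A reliably locks onto the IED in *time* (the spike transient is
broadband and strongly modulates pairwise phase statistics), and
within-pair directionality at a known frequency is recovered essentially
always (bias cancels between the two directions of one pair), but the
point-A *frequency* reflects the estimator's bias structure — it is
stable across epochs of one dataset rather than equal to the injected
carrier. The dedicated acceptance check of carrier-frequency recovery is
therefore expected to fail and is retained as an honest negative;
downstream zone statistics are unaffected because every epoch uses its
own point-A band consistently across all electrodes.

**Other limitations.** With a common average reference on a small
montage (16 channels), the reference itself carries a sizable share of
the IED and injects it into every channel; the zone contrast survives at
the default conditions, but EZ–MZ separation is noticeably weakened
compared to EZ–NZ. Logistic accuracy is evaluated in-sample and therefore optimistic
by construction; no cross-validation is performed, matching the
reference usage. The exact Mann–Whitney switch
applies only to untied samples; ties always use the corrected normal
approximation. PTE values are reported without surrogate-based
significance, which is out of scope.

## Problem sizes used in checks

The packaged checks run the full pipeline at the generator defaults (16
channels, 30 epochs; about a minute), 100 random digraphs (N ≤ 8)
against the graph oracles, 200 seeded windows each for directionality
and the dPTE null, and 50 seeded epochs for the point-A construction.
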