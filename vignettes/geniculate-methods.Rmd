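---
title: "Models and methods behind geniculate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind geniculate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(geniculate)
```

geniculate characterizes visual responses of LGN neurons from spike trains
recorded under three stimulus classes — drifting sinusoidal gratings,
full-field flicker, and a contrast-modulated spatiotemporal noise movie —
and validates every estimator against a synthetic population with known
ground truth. This vignette explains the models, the tunable parameters,
the numerical choices, and what the simulation does and does not establish
about real recordings.

## Stimuli

**Grating protocols.** Four parameter sets probe one axis each while the
others stay at standard values (0.03 c/deg, 1 Hz, 0.98 contrast, 0°
direction): ten spatial frequencies from 0.02 to 0.96 c/deg (6 repeats,
7 s trials), ten temporal frequencies from 0.3 to 9.6 Hz (4 repeats, 14 s),
six contrasts from 0.10 to 0.98 (10 repeats, 7 s), and eight directions at
45° spacing (6 repeats, 7 s). Every trial is flanked by 1 s of blank
screen, and the whole trial list is presented in a seeded pseudorandom
permutation. `flicker_protocol()` alternates 600 ms full-field white and
black epochs (800 per standard session).

**Noise movie.** `generate_noise_movie()` builds the mapping stimulus in
the Fourier domain: a white Gaussian field is shaped so its spatial
amplitude spectrum falls off as $A(f) \propto 1/(f + f_c)$ with
$f_c = 0.05$ c/deg and a hard cutoff at 0.16 c/deg, and its temporal
spectrum is flat with a sharp 10 Hz low-pass cutoff. The DC component is
forced to zero so the mean is exactly mid-grey. Frame size (64 × 64 px),
degree calibration (1 deg/px, covering roughly ±30°) and frame rate
(30 Hz, comfortably above twice the temporal cutoff) are not dictated by
the stimulus definition and are configurable; the defaults are stated
here as the package's own choices. The contrast envelope is
$E(t) = \tfrac12\,(1 - \cos 2\pi \cdot 0.1\,t)$ — a full-wave sinusoid
with 10 s period that starts at zero contrast, avoiding an onset
transient. The zero-mean noise is scaled so that 3 RMS spans the [0, 1]
intensity range and residual excursions are clipped; the clipped fraction
(~0.3% of samples at the default scaling) is recorded in the
`clip_fraction` attribute. Clipping leaves a tiny broadband residue, which
is why the spectral tests assert out-of-band power below 0.1% of the total
rather than exactly zero.

## The synthetic LNP population

`sample_population()` draws neurons whose every response axis follows the
same parametric family the analysis fits:

* spatial receptive field: signed 2D Gaussian, mean radius uniform on
  4–9 deg (population median near 6.5 deg), radius ratio 0.85–1.18;
* spatial-frequency tuning: difference of Gaussians with centre radius
  2.2–4 deg, surround 3.5–6 × larger, relative surround strength
  0.65–0.92 — preferred frequencies near 0.035 c/deg;
* temporal-frequency tuning: two half-Gaussians with peak 2.2–4.5 Hz.
  The width is drawn jointly with the peak ($s \ge (p-1)/1.2$) and the
  low-side baseline fraction is 0.05–0.2, so the standard 1 Hz probe used
  by the other grating protocols always drives the cell appreciably; with
  independent draws, a neuron with a high, narrow peak would be nearly
  silent at 1 Hz and none of its other axes would be measurable —
  inconsistent with observed low50 medians near 1.4 Hz;
* contrast response: Naka–Rushton with $h$ 0.35–0.65 and exponent
  1.8–3.5 (C50 near 0.5);
* direction tuning: a multiplicative von Mises gain in $\theta$ (DS) or
  $2\theta$ (OS), with the concentration solved numerically so the
  noise-free 8-direction vector-sum index equals the drawn target
  (0.6–0.8 DSI for DS cells, 0.8–0.9 OSI for OS cells, 0.02–0.08 for the
  rest). Because the discrete 45° sampling grid caps the attainable OSI at
  $\cos(2\,\Delta)$ for a preferred orientation offset $\Delta$ from the
  grid, selective cells are drawn with preferred directions within ±10° of
  the probe axis; this also keeps their spatial-frequency and linearity
  axes measurable under the fixed-direction protocols;
* linearity: the temporal modulation of the grating drive is
  $M(t) = \max(0,\, 1 + m \cos 2\pi f t)$, rescaled to unit mean. With
  $m = 1$ the noise-free F1/F0 is exactly 1 — the classification boundary —
  so the generator uses $m = 2$ for linear cells (rectified
  over-modulation, noise-free F1/F0 ≈ 1.32) and $m = 0$ for nonlinear
  cells (F1/F0 ≈ 0), placing both classes well away from the threshold;
* flicker adaptation: within preferred-polarity epochs the rate is
  $spont + step\,(s_f + (1 - s_f)e^{-t/\tau})$. Transient cells use
  $\tau$ 10–25 ms with sustained fraction ≤ 0.15 (index well above 1);
  sustained cells use a sustained fraction slightly above 1 (a shallow
  onset dip), since a perfectly flat rate gives index exactly 1 — again
  the boundary — and could not be classified reliably under Poisson noise.

Spiking is an inhomogeneous Poisson process sampled by thinning. The movie
pathway projects each frame (as deviation from mid-grey) onto the signed
receptive field, convolves with a biphasic difference-of-exponentials
kernel (peak latency 50 ms by default — the temporal kernel is a modelling
choice, not a measured quantity), scales the drive to a target standard
deviation (`movie_drive_sd`, default half the evoked rate, chosen so a
300–500 s movie yields the few thousand spikes an STA needs), rectifies
about the spontaneous rate, and draws Poisson counts per frame.

**What passing these simulations shows — and what it does not.** The
synthetic population exercises estimator correctness: unbiased STA
recovery, exact fit recovery in the noise-free limit, correct
classification at the stated thresholds under Poisson variability. Real
recordings add spike-sorting contamination, non-Poisson firing (bursting,
refractoriness), eye movements, slow drifts in responsiveness, and
space–time-inseparable receptive fields; none of these are modelled, so
recovery rates here are upper bounds on real-data performance.

## Receptive-field estimation

The STA is computed at every lag on the frame grid within 0–300 ms and the
lag with the largest absolute peak is kept. Because the movie is spatially
correlated, the raw STA equals the receptive field blurred by the stimulus
autocorrelation; for a Gaussian field of radius $\sigma$ the blur inflates
the fitted radius by roughly $\sqrt{\sigma^2 + \sigma_k^2}/\sigma$, a
20–40% bias at small radii. `compute_sta()` therefore divides the map's
Fourier transform by the known stimulus power spectrum inside the pass
band (Tikhonov-regularized, $\lambda = 0.05$ of the peak power — the
classical inverse-correlation correction), then smooths with a Gaussian of
known width (3 px). The smoothing suppresses the noise that whitening
amplifies; since its kernel is known exactly, `fit_gaussian2d()` subtracts
its width from the fitted radii in quadrature, so it costs no bias. The
contrast envelope is not corrected for: it multiplies every frame uniformly
and averages out of the STA.

The 2D Gaussian fit is bounded Levenberg–Marquardt with an additive offset
as a free nuisance parameter (initialized at the map median, absorbing
grey-level bias, not reported), five jittered restarts, best residual wins.
The reported radii are the Gaussian standard deviations in degrees.

## Tuning fits and derived metrics

All three families are fit by bounded Levenberg–Marquardt with ten jittered
multi-starts under fixed seeds; `rs > rc` is enforced by parameterizing
$\log(r_s/r_c)$. Variance explained is $1 - SS_{res}/SS_{tot}$ on the
trial-mean rates, and only fits with VE ≥ 0.95 (inclusive) enter
population analyses. Spontaneous rate is *not* subtracted before fitting —
the curves are raw rates with the blank-derived spontaneous level carried
alongside — and is subtracted only where an index definition requires it
(vector-sum selectivity, F1/F0).

Conventions that the definitions leave open, fixed here and isolated in
single functions:

* the spatial-frequency cutoff is where the *baseline-subtracted* fitted
  response falls to 1% of its baseline-subtracted peak, found by bisection
  above the peak;
* the temporal low50/high50 solve $R(\omega) = a/2$ on the *absolute*
  scale (closed form $p \pm s\sqrt{\ln\!\big((a-b)/(a/2-b)\big)}$). A side
  whose baseline exceeds $a/2$ never reaches half-maximum; that bound is
  undefined and forces the pass-band class. On the baseline-subtracted
  reading the half-height would always exist and the documented
  undefined-bound case could never occur, which is why the absolute
  convention is taken as the operative one;
* contrast metrics are baseline-subtracted: $c_{20}$ and $C_{50}$ solve
  $R(c) - b = q\,(R(1) - b)$ for $q = 0.2, 0.5$ (closed form in the
  Naka–Rushton parameters), and the gain is the analytic derivative
  $dR/dc$ at $c_{20}$;
* low/band/high-pass classes follow the fitted peak position against the
  tested range: at or below the lowest tested value is low-pass, at or
  above the highest is high-pass, between is band-pass — threshold-free
  and directly testable.

A subtlety of the fixed trial lengths: at drift frequencies whose period
does not divide the trial (e.g. 0.3 Hz in 14 s), the trial-mean of a
modulated rate carries a small cycle-truncation distortion (order 1%), so
exact noise-free recovery holds for unmodulated drive and recovery for
modulated cells is correct to within that distortion.

## Indices and thresholds

Vector-sum DSI/OSI use spontaneous-subtracted mean rates, with negative
values clipped to zero (a negative weight would make the normalizer
ill-defined). Thresholds are strict: DSI > 0.33, OSI > 0.6. F1 uses the
peak-sinusoid amplitude convention ($2|X_1|/N$ of the cycle-averaged rate,
1 ms bins), under which a raised-cosine rate has F1/F0 exactly 1, matching
the interpretation of 1 as the modulation threshold; spontaneous rate is
subtracted from F0 only, since a constant shifts only the DC term. The
transient/sustained index takes the epoch PSTH of the preferred flicker
polarity (auto-detected as the color with more spikes unless given) with
no latency correction by default (a configurable offset exists); index
exactly 1 classifies as sustained ("fell below" complemented by "above"
for transient). F1/F0 is evaluated at the tested spatial frequency closest
to the fitted preferred one, falling back to the best-driven frequency
when the spatial fit is excluded.

## Statistics

Normality is assessed with a hand-implemented D'Agostino–Pearson omnibus
test (standardized skewness and kurtosis, $K^2 \sim \chi^2_2$), validated
against reference values; it is applied only when $n > 30$, and smaller
samples take the nonparametric path unconditionally. Two-group comparisons
use Welch's t-test when both groups are large and pass normality,
otherwise Mann–Whitney (exact when the smaller group has ≤ 8 observations
and no ties); three or more groups use Kruskal–Wallis. No multiple-testing
correction is applied, and the report metadata says so.

## Pipeline and problem sizes

`run_simulate() → run_characterize() → run_report()` exchange plain files
(CSV/JSON; movies as RDS — see `inst/FORMATS.md`) and fan a single global
seed out to per-stage seeds through a fixed counter scheme, so every stage
is independently reproducible and the whole pipeline is byte-deterministic
given a config. The packaged validation runs at desk scale, chosen so the
full battery completes in minutes on one core while keeping every estimate
well-conditioned: 12–24 neurons, the standard grating repeat counts, a
single 240–480 s movie block at 64 × 64 px for receptive-field mapping
(several thousand spikes per neuron), and 800 flicker epochs. The
acceptance script reports, for each quantity, the problem size it was
computed at.

## Known limitations

Space–time-separable receptive fields only; no surround estimation from
the STA (the surround enters through the spatial-frequency fit); Poisson
spiking without refractoriness or bursting; direction tuning acts as a
multiplicative gain, so the simulator makes no claim about the mechanism
of direction selectivity; the flicker pathway models adaptation as a
single exponential. The hyperbolic contrast family is monotone by
construction, so genuinely non-monotone contrast responses are flagged by
the variance gate rather than modelled.
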