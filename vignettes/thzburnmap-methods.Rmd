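---
title: "Methods: simulating and grading THz reflection scans of burn wounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and grading THz reflection scans of burn wounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Terahertz time-domain spectroscopy (THz-TDS) measures the electric-field
waveform of a picosecond pulse reflected from tissue. Because THz
reflectivity is dominated by tissue water content, the interstitial edema
that forms within an hour of a burn raises the refractive index of the
injured skin, and with it the reflection from the imaging-window/skin
interface. `thzburnmap` implements a full analysis chain for grading burn
wounds from such scans into superficial partial-thickness (SPT, dermal
burn depth $d < 40\%$), deep partial-thickness (DPT, $40\% \le d \le
80\%$) and full-thickness (FT, $d > 80\%$) classes, together with a
physics-based simulator that generates scan cubes with known ground truth.
The simulator exists because no public in vivo scan data are available at
this level of rawness; every stage of the analysis is exercised against
simulated cubes whose construction is documented here.

## The forward model

Each pixel's waveform is the incident pulse filtered by the reflection
transfer function of a window-backed sample:

$$H(f) \;=\; r_b(f)\sum_{m=0}^{M} \left(r_t\, r_b(f)\right)^m
  e^{\,i 2\pi f m T},\qquad T = \frac{2 n_w \ell}{c},$$

where $r_b$ is the normal-incidence Fresnel coefficient of the
window/backing interface, $r_t$ the internal window/air coefficient of the
top face, $n_w$ and $\ell$ the window index and thickness, and $M$ the
number of modelled Fabry–Pérot echoes. Echo orders whose delay exceeds
the time record are dropped rather than circularly wrapped. The common
entry/exit transmission factor is normalized out; it cancels in
deconvolution against the reference.

Skin permittivity follows the double-Debye model standard for water-rich
tissue at THz frequencies,

$$\epsilon(\omega) = \epsilon_\infty
 + \frac{\epsilon_s - \epsilon_2}{1 - i\omega\tau_1}
 + \frac{\epsilon_2 - \epsilon_\infty}{1 - i\omega\tau_2},$$

with defaults from a published in vivo healthy human skin parameterization
($\epsilon_s = 60.0$, $\epsilon_2 = 3.6$, $\epsilon_\infty = 3.0$,
$\tau_1 = 10.6$ ps, $\tau_2 = 0.18$ ps). These are plausible for mammalian
skin; no claim is made of matching any particular animal. The sign
convention is $e^{-i\omega t}$ (loss = positive imaginary part), conjugated
when responses are applied on the FFT grid.

Burn severity enters through a hydration delta applied to the
slow-relaxation amplitude: $\epsilon_s \mapsto \epsilon_s + \delta\,
(\epsilon_s - \epsilon_2)$ with $\delta = \delta_{\max}\, d / 100$ and
$\delta_{\max} = 0.3$ by default (raising $\epsilon_s$ from 60 towards the
free-water value near 78 at full thickness). The mapping is deliberately
generic: no quantitative link between scald exposure and dielectric change
is established in the literature, so any monotone map reproduces the
qualitative edema mechanism, and the linear one is the simplest to
document. Punch-biopsy sites are modelled as window–air responses (the
4-mm punch leaves an air gap under the window) rasterized as 13-pixel
disks on the 1-mm grid.

### What the simulator emulates, and what it does not

Emulated: the 27 × 27 mm² field of view at 1 × 1 mm² pixels, 20 averages
per pixel (additive white noise of RMS `noise_rms`/√20), per-pixel
multiplicative reflectivity jitter standing in for scattering
heterogeneity of skin appendages (sd 0.03, motivating ROI averaging),
monotone severity contrast, Fabry–Pérot window echoes, and biopsy air
gaps. Not emulated: beam propagation and focusing optics, angular or
polarization effects, depth-resolved multilayer skin structure, wound
boundary irregularity, motion artifacts, or day-to-day registration.
Passing tests therefore demonstrate the correctness and calibration of the
*algorithms* under a faithful reduced physics, not clinical performance on
real scans.

Wounds are square footprints (half-width `radius`) rather than disks so
that 4 × 4 ROI blocks always have admissible positions inside even small
phantom wounds; biopsy disks remain circular. The default study is ten
single-burn scans (one wound per field of view, as scanned in practice)
with $d$ = 10, 22, 30, 45, 55, 65, 75, 85, 92, 97, spanning the three
grades.

### Acquisition geometry

The default record is 160 ps sampled at 0.025 ps (Nyquist 20 THz), pulse
peak at 30 ps, window $n_w = 1.95$, $\ell = 4$ mm (round trip 52 ps,
echoes at 82 and 134 ps). This layout was chosen from the wavelet support
arithmetic: the level-6 sym8 equivalent filter spans about ±12 ps, and
both noise windows (pre [1, 13] ps, post [47, 65] ps) keep more than 14 ps
of clearance from the pulse and echo supports. Because the filters have
compact support, a noiseless record then yields *exactly* zero coefficients
inside the windows at every level, so the level-dependent thresholds
measure noise alone and a clean waveform passes through denoising
unchanged. On a shorter record (or a thinner window) the post-pulse window
cannot clear the deepest level's support between the pulse and the first
echo, and signal energy leaks into the thresholds.

## Denoising

Waveforms are denoised by maximal-overlap discrete wavelet transform
(MODWT, implemented by exact FFT-domain circular filtering with embedded
sym8/db4/haar filters) with *level-dependent hard thresholding*: for each
detail level the threshold is the maximum coefficient magnitude over the
two noise windows, after compensating the level's group delay (measured
from the equivalent filter's impulse response). Coefficients at or below
the threshold are zeroed; all others, and the final-level approximation,
are untouched. The max rule guarantees the noise windows are zeroed at
every detail level and is homogeneous of degree one in the noise
amplitude. A $k\sigma$-style rule was considered and rejected as the
default because the max rule gives the cleanest contract ("the windows
define what noise looks like; remove everything at that scale").

Consequences worth knowing: noise in the approximation band (below
Nyquist/2⁶ ≈ 0.31 THz) is never removed, so the expected noise-window RMS
reduction is $\sqrt{2^6} = 8$; and any genuine signal weaker than the
noise floor is removed along with the noise. Hard (not soft) thresholding
keeps surviving coefficients unbiased, which is why the pulse peak changes
by well under 1%.

## Deconvolution

Per-pixel reflectivity spectra come from Wiener deconvolution against the
window–air reference,

$$R(f) = \frac{S_{\mathrm{samp}}(f)\,\overline{S_{\mathrm{ref}}(f)}}
  {|S_{\mathrm{ref}}(f)|^2 + 1/\mathrm{SNR}(f)},$$

with $\mathrm{SNR}(f) = |S_{\mathrm{ref}}(f)|^2 / P_{\mathrm{noise}}(f)$
estimated from the smoothed periodogram of the pre-pulse window rescaled
to the record length. The SNR is clipped at 10⁶ so the noiseless limit
stays finite, and floored at 10⁻¹² so it is strictly positive. The plain
spectral ratio is retained (`naive_deconvolve()`) as a comparison mode; it
diverges where the reference spectrum has no energy, which is the artifact
the Wiener term suppresses. The simulated reference is the time-gated
primary window–air reflection (flat Fresnel coefficient times the incident
pulse, no echoes), the standard practice for a deconvolution reference;
deconvolved spectra are therefore the sample transfer function normalized
by $r_{wa}$, and a noiseless pixel recovers the closed-form magnitude to
better than 0.01% in band.

## Biopsy masking from the Fabry–Pérot echo phase

Each window round trip multiplies the field by $r_t\, r_b$. For an air gap
$r_b = r_t > 0$, so the first echo is in phase with the pixel's primary
reflection; for water-rich skin the loss term makes $\mathrm{Re}(r_b) < 0$
across the band, so the echo is phase-reversed relative to the primary.
The detector gates the primary pulse and the first-echo segment (±5 ps
around the nominal round-trip delay) and tests the sign of their
correlation; a non-negative sign (air-like phase) marks a biopsy pixel.
Note the *absolute* echo sign is uninformative — the first echo scales as
$r_b^2 r_t$, which is even in $r_b$ — so the phase must be referenced to
the pixel's own primary, which is also why a correlation against the
reference echo template alone would not discriminate. At the default noise
level the healthy-skin statistic sits about 6 standard deviations below
zero, giving pixel-perfect masks on the default phantom.

## Features and observations

Images are formed as the per-pixel trapezoidal area under $|R(f)|$ between
0.1 and 0.5 THz (endpoints inclusive on the FFT grid; 65 bins at the
default grid), normalized to a maximum of one over the field of view.
Observations for classification are built from fifteen 4 × 4-pixel ROIs
drawn uniformly (without replacement of top-left positions) from the
admissible positions inside each wound footprint, excluding any block that
touches a biopsy pixel; ROI–ROI overlap is permitted, matching random
selection over a wound, and a `disjoint` flag forces non-overlap when
wanted. Each ROI contributes one row: the mean of its sixteen pixel
amplitude spectra restricted to the in-band bins (the classifier's
predictor space) plus the scalar band area (for images and the ANOVA).

## Classification harness

Six families are evaluated as three independent one-vs-all binary
problems: linear / polynomial (degree ∈ {2, 3, 4}) / Gaussian-kernel SVM,
naive Bayes (Gaussian or kernel densities, scored in log space), LDA
regularized by shrinking the pooled covariance towards a scaled identity
($\gamma \in [0, 1]$), and discrete AdaBoost over weighted regularized-LDA
learners. Hyperparameters are tuned per outer fold by a compact Bayesian
search (Gaussian-process surrogate, expected improvement, 30 evaluations
by default) whose objective is the *inner-CV misclassification loss* at
the native decision boundary, with inner-CV AUC as a small tie-break. The
loss objective matters: on separable folds an AUC-only objective cannot
distinguish a well-placed boundary from a degenerate constant-score model,
and the degenerate model poisons the pooled ROC. The Gaussian/polynomial
kernel scale $s$ is searched on $[10^{-2}, 10^{2}]$ (log-uniform) with
$K = \exp(-\|x - x'\|^2 / s^2)$, the box constraint on $[10^{-3},
10^{3}]$.

Outer folds are fivefold, stratified by class at the observation level by
default, so ROIs from one burn may cross folds — matching the apparent
study protocol. This leaks burn identity: overlapping ROIs of one burn
share pixels, so even a zero-contrast study is classified above chance.
The leakage-safe alternative (`burn_grouped = TRUE`) assigns whole burns
to folds and restores chance-level AUC under zero contrast; it is the
right mode for inference about generalization across wounds, while the
default mode reproduces the reference protocol. Test scores are pooled
across the five folds before the ROC is built; sensitivity, specificity
and accuracy are computed at score 0 (the classifier's native boundary),
since no other operating point is documented. ROC ties receive half
credit (Mann–Whitney convention), making the threshold-sweep AUC equal to
brute-force concordant-pair counting. The whole evaluation repeats over
ten ROI-randomization iterations by default, reporting mean ± sd.

A consequence of the one-vs-all construction: DPT is a *middle* class, so
no monotone (linear) score can rank it against both neighbours at once.
Stronger severity separation actually lowers the linear SVM's DPT AUC
while the Gaussian kernel tracks it — the package's signal-ordering test
asserts monotonicity in the separation scale for the Gaussian family (and
for the linear family only on the outer classes), and Gaussian ≥ linear
per class at nominal separation.

Group differences in band area are tested by one-way ANOVA at α = 0.05
with Tukey–Kramer pairwise comparisons (the reference analysis reports
pairwise p-values without naming an adjustment; Tukey–Kramer is the
standard choice after an omnibus one-way ANOVA).

## Numerical and design choices

- **Problem sizes.** The bundled tests run the full chain at reduced
  sizes chosen once as a deliberate design of the test fixtures: the tiny
  fixture is three 9 × 9 single-burn scans (3 ROIs × 3 iterations); the
  signal-ordering study uses six 15 × 15 scans, 12 ROIs, 3 iterations and
  16 search evaluations; the acceptance script runs the default ten-burn
  27 × 27 study with 15 ROIs, 3 iterations and 12 search evaluations.
- **Determinism.** Every random draw descends from a seed: scan noise
  from `scan_config$seed`, ROI draws / folds / searches from the harness
  seed, pipeline stages from `master_seed`. Reruns with one master seed
  are bit-identical (checksummed in the manifest).
- **Degenerate inputs.** SNR estimation clips at 10⁶ (noiseless) and
  floors at 10⁻¹²; standardization guards zero-variance features;
  single-class training data, all-masked grids, missing upstream
  artifacts, echoes outside the record and invalid bands all fail with
  explicit messages before any computation.
- **Containers.** Scan cubes live in a plain-text directory container
  (CSV matrices + JSON metadata) behind `write_scan()`/`read_scan()`;
  observation tables, metrics and ROC samples are CSV; summaries and the
  run manifest are JSON; pipeline configuration is YAML and round-trips
  unchanged.

## Known limitations

Single-layer skin (no depth-resolved dielectric profile); frequency-flat
lossless window; normal incidence only; the hydration map is generic by
construction; classifier AUCs on the simulator's default conditions are
near-saturated (the synthetic contrast is cleaner than in vivo data, where
the reference study reports AUCs near 0.9); and the default fold mode
shares burns across folds, which is faithful to the reference protocol but
optimistic about cross-wound generalization — use `burn_grouped = TRUE`
for the conservative answer.
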