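---
title: "Multi-channel SCOS processing: models, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-channel SCOS processing: models, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scosr)
```

# The measurement

Speckle contrast optical spectroscopy (SCOS) infers blood-flow changes from
the blurring of laser speckle integrated over a camera exposure. Coherent
light diffusing through moving scatterers produces a speckle pattern whose
spatial contrast

$$K = \frac{\mathrm{std}(I)}{\langle I \rangle}$$

decreases as scatterer motion speeds up relative to the exposure time $T$.
For a field decorrelating as $g_1(\tau) = e^{-\tau/\tau_c}$, the
fundamental (tissue-dynamics) contrast squared follows

$$K_f^2(\beta, x) = \beta\,\frac{e^{-2x} - 1 + 2x}{2x^2}, \qquad
  x = T/\tau_c,$$

implemented in `expected_contrast()`. $\beta$ is the system coherence
parameter — the $x \to 0$ ceiling set by source coherence, mode count and
polarization mixing. For unpolarized detection it is fixed by the
amplitude ratio $s/p$ of the two detected polarization speckle fields,

$$\beta = \frac{(s/p)^2}{2\,\bigl(1 + (s/p)^2\bigr)},$$

(`beta_from_sp()`, inverse `sp_from_contrast()`). The instrument this
package models measures $s/p \approx 0.69$, hence $\beta \approx 0.16$.
The single-exponential field-correlation form is the community-standard
model for diffusing scatterers; it is a modeling choice, and everything
downstream treats it as the definition of the simulator's ground truth.

A multi-channel instrument multiplexes one laser over 7 source fibers (10
ms slot each, 5.2 ms illumination, 4 ms camera exposure at 100 Hz), giving
a 5.2/70 = 7.4% per-source duty cycle and a 100/7 = 14.3 Hz full-array
rate (`multiplex_schedule()`, `duty_cycle()`, `full_array_rate()`).
Detector fiber bundles project onto 10-bit CMOS cameras (black level 25
ADU, read noise 2.1 e-; `camera_spec()`).

# Noise-corrected contrast

Raw windowed contrast is inflated by camera noise. After dark subtraction,
pixels are grouped into 7x7 windows and, per window and frame
(`window_statistics()`, `contrast_components()`):

$$K_{raw}^2 = \frac{\sigma^2_{window}}{\langle I_{window}\rangle^2},\quad
  K_s^2 = \frac{G}{\langle I_{window}\rangle},\quad
  K_r^2 = \frac{\langle\sigma^2_{dark}\rangle - 1/12}{\langle I_{window}\rangle^2},\quad
  K_q^2 = \frac{1/12}{\langle I_{window}\rangle^2},\quad
  K_{sp}^2 = \frac{\sigma^2_{meanimage}}{\langle I_{meanimage}\rangle^2}$$

$$K_{f,window}^2 = K_{raw}^2 - K_s^2 - K_r^2 - K_q^2 - K_{sp}^2$$

where $G$ is the camera gain in ADU per photoelectron (calibrated from the
photon transfer curve, `estimate_gain_ptc()`), $1/12$ ADU$^2$ is the
variance of rounding to integer ADU, and the spatial-heterogeneity term
uses the per-source temporal mean image. Windows are combined per frame
with squared-intensity weights $w = \langle I\rangle^2 / \sum \langle
I\rangle^2$ (`weighted_kf2()`), so bright windows dominate.

Two derived time courses feed the analysis:

* $\Delta OD = -\ln(I/I_0)$ (`delta_od()`), sensitive to absorption (blood
  volume); natural logarithm throughout.
* $rD_B - 1 = K_{f,0}^2 / K_f^2 - 1$ (`rdb_minus_one()`), the fractional
  change of the effective scatterer diffusion coefficient, i.e. the
  blood-flow index.

Baseline conventions: for continuous runs $I_0$ and $K_{f,0}^2$ default to
the whole-run mean; block analysis re-references each epoch to its own
-2..0 s pre-stimulus window. Both are configurable. Note that with
$K_{f,0}^2$ defined as the temporal mean of $K_f^2$, the baseline-interval
mean of $rD_B - 1$ is zero only up to a Jensen term
$\overline{K_{f,0}^2}\cdot\overline{1/K_f^2} - 1 \geq 0$; it vanishes
exactly for a constant series and is second order in the baseline
fluctuations otherwise.

## Finite-window estimator bias

With 49 pixels per window the ratio statistic
$s^2/\bar m^2$ carries an $O(1/49)$ small-sample bias whose size depends
on the third moment of the speckle intensity distribution: about $-1.5\%$
for the physical two-polarization mixture at $\beta = 0.16$, about
$-0.1\%$ for Gamma-distributed intensities. The correction equations above
do not (and are not meant to) remove it — it is a property of the
windowed estimator, identical in the real instrument. Consequently the
package's recovery tests of the *noise corrections* compare the full
camera pipeline against the expectation of the same windowed statistic on
noiseless speckle (an independent Monte Carlo oracle), while calibration
checks against the closed form ($\beta$, $s/p$) use tolerances that
accommodate the documented bias. Ratio quantities such as $rD_B - 1$ and
flux-invariance comparisons are unaffected, because the bias cancels.

# The synthetic frame generator

`simulate_frames()` emulates the instrument so every stage is testable
without hardware. Per frame, the active source's speckle factor (mean 1)
scales the commanded photoelectron flux and an optional smooth
illumination-heterogeneity map (`heterogeneity_map()`, default a random
quadratic surface with 5% RMS, emulating defocused fiber-bundle
illumination); photoelectrons are Poisson, ADU conversion applies the
gain, black level and Gaussian read noise, then rounding and clipping to
the bit depth. Two speckle generators are provided:

* **gamma** (default, fast): per-pixel intensities from a Gamma law whose
  relative variance equals $K_f^2(\beta, x)$ exactly.
* **field** (gold standard): two complex-Gaussian polarization components
  with power ratio $(s/p)^2$, each evolving as a first-order
  autoregressive process with sub-step correlation $e^{-\Delta t/\tau_c}$
  and integrated over the exposure in at least 20 sub-steps. The sub-step
  count is raised until the discrete-sum contrast matches the continuous
  closed form to < 0.1%. Because the two-component sum has a contrast
  floor of 0.5, arbitrary $\beta < 0.5$ is reached by mixing the speckle
  with a static background — contrast scales with the square of the
  speckle fraction, so the target $\beta$ is hit exactly while keeping
  genuine field statistics.

Frames are drawn independently in time (the 70 ms source revisit interval
is far longer than the millisecond-scale decorrelation times of interest);
a static scene ($\tau_c = \infty$) freezes one pattern, as a static
phantom does. The seed drives separate streams for field dynamics and
detection noise, so runs at different flux share identical speckle — the
basis of the flux-invariance tests. What the generator does **not**
emulate: spatial speckle correlations across pixels (speckle grain is one
pixel), absorption-dependent sensitivity changes, motion artifacts beyond
injected spikes, photon transport through layered tissue, and any
galvanometer/laser hardware dynamics. Passing recovery tests therefore
validate the estimator chain, not photon-migration physics.

For static scenes the temporal mean image *is* the speckle pattern, so the
heterogeneity term is meaningless there; `contrast_components(ksp =
"none")` matches the instrument practice of skipping it for static
calibrations, and is also appropriate for simulations with uniform
illumination. The mean-image statistic from $N$ frames over-estimates the
true heterogeneity by the residual per-pixel variance divided by $N$; the
tests account for this known floor explicitly.

The galvanometer coupling search (`galvo_search()`) reproduces the staged
procedure used to locate each fiber on a synthetic coupling landscape:
spiral until a power threshold, alternating +/-20 um line scans per axis
until no improvement, then a ~40x40 um grid refinement. All stages sample
on a 5 um grid with ties broken toward the earlier-scanned point; the
exact spiral geometry is unspecified in the source procedure, so an
Archimedean ring walk bounded at 500 um is used.

# Probe geometry

`hd_probe_layout()` returns the canonical 7-source / 17-detector layout: a
triangular lattice over a 76 mm x 66 mm footprint, five rows 16.5 mm
apart, nearest-neighbor spacing 19.04 mm, plus a short-separation detector
8 mm from source 7. This assignment was derived to satisfy every printed
constraint of the instrument's grid — footprint, 19/33 mm separation
classes, and exactly 28 near / 22 far channels (`enumerate_channels()`,
+/-0.5 mm class bands). The true instrument assignment may differ in
which lattice nodes are sources; only the class separations and counts are
treated as ground truth. Coordinates are flat scalp-plane millimeters; no
head curvature. The 9 mm minimum spacing (holder size) is enforced for
grid optodes; the short-separation detector is exempt because its holder
mounts around the source grommet.

# Channel-space analysis

The human-data chain (`prune_low_flux()`, `detect_motion_blocks()`,
`short_sep_regress()`, `lowpass()`, `block_average()`, `group_stats()`):

1. Channels averaging under 4 ADU are excluded (photon-transfer
   nonlinearity at low counts).
2. Motion artifacts — high-amplitude, high-frequency spikes — are detected
   automatically as a stand-in for manual review: each channel is
   high-passed above 0.5 Hz, converted to robust z scores
   (median/MAD), and any block in which any channel exceeds 5 MAD is
   masked. A manual mask always takes precedence; subjects with more than
   50% masked blocks are flagged for exclusion.
3. The 8 mm short-separation channel, dominated by scalp physiology, is
   regressed out of every 19/33 mm channel by OLS on the continuous
   series. The source procedure mentions a regression both on continuous
   signals and on block-averaged epochs; the package applies the
   continuous-series pass by default and leaves the epoch-level pass as an
   explicit optional second call, guessing neither intent.
4. A fifth-order Butterworth low-pass at 0.2 Hz, applied
   forward-backward (zero phase, so the 10-15 s activation window is not
   delayed). The series is extended by odd-symmetric reflection
   (15 cycles of the cutoff period) before filtering so no startup
   transient reaches the data.
5. Blocks are epoched from -2 to 38 s around onsets, shifted by their own
   -2..0 s baseline mean, and averaged per condition over valid blocks.
6. Group statistics weight subjects by valid-block counts,
   $w_i \propto n_i$; the weighted standard error is
   $\sqrt{\tfrac{n}{n-1}\sum_i w_i^2 (x_i-\bar x_w)^2}$, which reduces to
   $sd/\sqrt{n}$ under equal weights so the significance flag
   (window-mean over the closed interval [10, 15] s exceeding 1.96 SE)
   coincides with the classic one-sided t threshold; a two-tailed
   one-sample t-test p-value is reported alongside. The 1.96 rule is
   applied to the weighted mean, consistent with the averaging rule.

A note on power: at the group-level activation regime the cohort
simulations are calibrated to (effect 3.5%, between-subject SD 5.03%,
n = 15 — an observed t of about 2.7), the per-channel detection
probability of the 1.96 SE rule is `1 - pt(1.96, 14, ncp = 2.69)` = 0.77.
The package's cohort Monte Carlo measures exactly this (~0.77 sensitivity
at ~3.5% false-positive rate over 200 replicates); a 90% per-channel
sensitivity is not attainable in this regime and the corresponding
acceptance check reports the shortfall rather than relaxing the
conditions.

For phantom-style runs, `pca_common_mode_regress()` removes fluctuations
extraneous to the medium: within each group of channels sharing a source,
principal components whose loading coefficients have a coefficient of
variation below 1 across channels (i.e. near-equal loading everywhere) are
projected out.

# Image reconstruction

`tikhonov_reconstruct()` inverts the linear channel-to-image model
$y = A x$ for the underdetermined case:

$$x = A^T (A A^T + \lambda I)^{-1} y, \qquad \lambda = \alpha b,$$

with $\alpha = 0.05$ and $b$ the largest eigenvalue of $AA^T$ (symmetric
eigensolver; the system is solved by Cholesky factorization, never an
explicit inverse; matches a dense ridge oracle to 1e-8). The same
operator and $\alpha$ serve both $rD_B-1$ and $\Delta OD$, whose
sensitivity profiles are derived from the same detected photons. Channel
data are inverted unweighted. Because photon-transport head-model
computation is out of scope, `toy_sensitivity()` builds a stand-in
operator: per channel a sum of two 3-D Gaussians along the source-detector
line at effective depth separation/2.5 (the one-half to one-third
sampling-depth rule), scaled so total sensitivity grows with separation.
Only the topology — midpoint peak, deeper sampling for wider separations,
<10 mm point-perturbation localization inside the footprint — is asserted,
never photon-transport accuracy.

# Numerical choices and degenerate inputs

* Unbiased ($n-1$) spatial variance inside windows (49 samples; the
  divisor is not dictated by the correction equations, so the standard
  choice is documented here).
* Edge pixels beyond the largest 7-divisible region are discarded —
  partial windows would carry different noise statistics.
* Missing frames detected from timestamps are re-slotted on the nominal
  schedule grid as all-NA markers, never interpolated, and propagate as
  NA through every downstream average; more than 10% missing is a hard
  error. The repair is idempotent.
* Windows with negative corrected $K_f^2$ (possible at low flux) are
  retained in the weighted sum — truncation would bias it — and a
  channel-frame is marked missing only if the aggregate is non-positive.
* Weights default to the per-source temporal mean image (stable); the
  per-frame alternative is available (`weights = "perframe"`) since the
  weighting definition admits both readings.
* Gain fitting is inverse-variance weighted least squares; levels with
  more than 1% clipped pixels are excluded automatically.
* Quantization is round-to-nearest then clip; its 1/12 ADU$^2$ variance
  matches the correction term.
* 16 dB of camera analog gain is *not* converted to ADU/e- (the
  conversion is camera-specific); the simulator takes the conversion gain
  directly, default 0.5 ADU/e-, which conditions the photon-transfer fit
  well across a 10-bit range.

# Scale of the validation suite

Test problem sizes are chosen so the whole suite runs in a few minutes on
one core while keeping Monte Carlo errors meaningful: recovery grids use
49x49-pixel sensors (49 windows) with 25-35 frames per condition across
flux {5, 20, 100} e-/px and $x$ {0.1, 1, 10}; static calibrations pool
~8600 frozen-pattern windows; the cohort Monte Carlo uses 200 replicates
of 15 subjects x 20 channels; the end-to-end demo simulates two detectors,
two sources, four blocks at 28x28 pixels. All tolerances are 3 Monte Carlo
SE unless a fixed tolerance is stated by the quantity itself.

# Known limitations

* No photon transport: the toy sensitivity operator is topological only,
  and channel contrast is generated directly rather than from layered
  tissue dynamics.
* Single wavelength; $\Delta OD$ alone cannot separate hemoglobin species.
* The speckle field generator draws frames independently; it cannot
  emulate frame-to-frame speckle correlation at decorrelation times
  comparable to the source revisit interval.
* Motion detection is a simple robust-z stand-in for expert review.
* No GLM/HRF regression and no real-time streaming; the windowed
  statistics are computed post hoc.
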