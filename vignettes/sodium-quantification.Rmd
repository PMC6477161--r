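---
title: "Quantitative sodium MRI: models, corrections and calibrated defaults"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative sodium MRI: models, corrections and calibrated defaults}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodiumq)
```

# The two-compartment sodium model

A voxel's sodium content splits between a small intracellular pool
(`[Na⁺]_IC`, default 12 mM, the midpoint of the physiological 5–15 mM
range) and a large extracellular pool (`[Na⁺]_EC`, default 145 mM, midpoint
of 135–155 mM). Tissue sodium concentration is the volume-weighted average

$$\mathrm{TSC} = f_{ic}\,[\mathrm{Na}]_{IC} + (1 - f_{ic})\,[\mathrm{Na}]_{EC},$$

so TSC decreases monotonically with the intracellular volume fraction
$f_{ic}$, which is the model's handle on cellularity. The phantom generator
(`makeSubject`) draws $f_{ic}$ per subject and compartment from Gaussians
clipped to $[0.02, 0.98]$ and fills the voxel maps exactly with this
weighting; the calibration tubes are noiseless ground truth at 20 and
80 mM.

Intracellular-weighted sodium (IWS) comes from an inversion-recovery scan
that suppresses — but does not remove — the long-$T_1$ fluid pool. Its
ground truth is

$$\mathrm{IWS} = A\, f_{ic}\,[\mathrm{Na}]_{IC} + B\,(1 - f_{ic})\,[\mathrm{Na}]_{EC},$$

capped voxelwise at TSC. The weights $A$ (bound-pool calibration weight)
and $B$ (extracellular leakage) are not free numbers: they are the ratios
of each pool's inversion-recovery steady-state weighting to the agar tube's
(`iwsWeights`), because the calibrated IWS map divides the tissue signal by
the tube signal. A pure "leakage-only" form ($A \equiv 1$) cannot be made
consistent with that measurement chain, which is why the generalised form
is used.

# Signal models and the acquisition simulator

Four protocols are simulated (`protocol`): a 90° spoiled gradient echo for
TSC (TR 100 ms), the 30°/60° pair for B1 mapping (same sequence), and a 90°
inversion-recovery gradient echo for IWS (TR 250 ms, TI 30 ms); all use
NEX 6, FoV 300 mm, an acquisition matrix of 50 reconstructed to 120. The
spoiled GE steady state is
$m_0 \sin\alpha\,(1-E_1)/(1-E_1\cos\alpha)$, $E_1 = e^{-TR/T_1}$
(`geSignal`); the IR steady state with an ideal (adiabatic, hence
B1-insensitive) inversion is solved in closed form in `irSignal`, including
the incomplete recovery over $TR - TI$. Each pool relaxes
mono-exponentially; biexponential $T_2^*$ decay during the 0.5 ms echo time
is neglected.

Transmit and receive reciprocity is assumed for the surface coil: a voxel
with relative field $r$ is excited at $r\,\alpha_{nom}$ and received with
sensitivity $r$, so the noiseless signal is proportional to
$[\mathrm{Na}]\cdot r\,\sin(r\,\alpha_{nom})$ times the relaxation factor.
The committed field model is
$r(d) = 0.1^{(d/120\,\mathrm{mm})^{p}}$ with $p = 6$: relative field 1 at
the coil surface, a broad usable plateau over the tissue (a per-patient
power adjustment places the anatomy of interest inside the usable region),
and the floor 0.1 at the 120 mm penetration depth. The exponent matters:
with a steep shoulder across the compartments, any local averaging in the
B1 chain acquires a signal-weighted spatial skew, and the arccos of the
dual-angle ratio becomes badly conditioned at the resulting low flip
angles.

Two acquisition modes share the same signal model. *Full* mode samples
k-space along a simplified 3D-cones trajectory — cone half-angles tiling
the sphere area-uniformly, one outward spiral per cone with pitch at the
Nyquist spacing $1/\mathrm{FoV}$, $k_{max} = 1/(2\,\Delta x)$ — adds
complex Gaussian noise averaged over NEX, and reconstructs by
density-compensated Kaiser–Bessel gridding (oversampling 2; kernel width 8
by default, which matches direct Fourier summation to ~$10^{-7}$; width 4
is the fast option at ~$4\times10^{-3}$). Density compensation uses
radial-shell volume over sample count, which grows as $|k|^2$ as expected
for this family. The adjoint used in reconstruction is the exact adjoint of
the forward interpolation, verified to machine precision. *Fast* mode skips
k-space entirely: it adds the complex noise per voxel and takes the
magnitude, which produces exactly the Rician/Rayleigh statistics the
correction chain expects, at a small fraction of the cost. Cohort-scale
results use fast mode; the cones chain is exercised by the calibration
readback and the cross-mode consistency test.

# The correction chain

The processing order is fixed and tested: SNR is measured on the raw
magnitude image (mean ROI signal over the standard deviation of a
background ROI), *then* the noise bias is removed by squared subtraction —
per axial slice, the mean squared background value is subtracted from the
squared image and the square root taken, clamping negative radicands at
zero. For Rayleigh background the subtracted floor converges to
$2\sigma^2$. The voxelwise estimator retains a small concavity deficit at
low SNR (its exact expectation at SNR 5 is 9.78 for a true signal of 10);
the ROI-level estimate in the squared domain is unbiased, and at the
pipeline's tissue SNRs the distinction is negligible.

B1 mapping uses the dual-flip-angle identity
$\alpha_{true} = \arccos\!\big(S_{60}/(2 S_{30})\big)$ on the noise-bias
corrected pair. Two regularisations, both config-exposed and on by
default, make this stable at realistic SNR:

* a first-order convexity debias of the ratio,
  $\mathbb{E}[S_{60}/S_{30}] \approx (S_{60}/S_{30})(1 + CV_{30}^2)$, using
  the measured background noise sd;
* normalized Gaussian smoothing of the ratio map (sd 1 voxel) over valid
  voxels before the arccos — the coil field varies over centimetres, so
  this suppresses the arccos noise amplification without biasing the
  field. Smoothing the *images* instead would weight the local ratio by
  signal intensity and skew it along the field gradient; smoothing the
  *scale map* after the arccos acts too late, after the nonlinearity has
  already biased low-flip voxels.

Voxels below a low-signal threshold (3× background sd) or with effective
imaging flips outside 10°–140° are marked invalid and stay missing through
all downstream maps and ROI statistics. An optional scale-map smoothing
exists but defaults to off.

The transmit/receive correction divides by
$\alpha_{true}\sin\alpha_{true}$ (radians, at the imaging flip). This is
exact in the $TR \gg T_1$ limit and is applied as such; at the actual
$TR/T_1 \approx 4.5$–6 of the committed defaults the residual saturation
mismatch between tissue and tubes is at the percent level and is absorbed
into the calibrated defaults below.

# Calibration to concentration and the committed defaults

The two in-FoV agar tubes give an exact two-point line from corrected
signal to mM (`fitCalibration`); applying it to the tube ROI means returns
20 and 80 mM identically, which is why the noiseless uniform-B1 readback of
the 80 mM tube is exact through the full cones chain. Negative calibrated
voxels are floored at zero and counted; B1-invalid voxels stay missing.

The generator's defaults *are* the study conditions, and each was fixed
once, by a documented procedure, before the acceptance thresholds were
evaluated:

* `f_ic` means and sds: solved in closed form so ground-truth cohort TSC
  means and sds equal the emulated cohort statistics (tumour 56.8 ± 19.1,
  muscle 33.2 ± 16.3 mM): mean $f = ([\mathrm{Na}]_{EC} - \mathrm{TSC}) /
  ([\mathrm{Na}]_{EC} - [\mathrm{Na}]_{IC})$, sd $= \mathrm{sd(TSC)}/133$.
* tumour–muscle pairing: the two fractions share a subject-level latent
  factor (correlation 0.9). Independent draws with the marginal sds above
  would make all-concordant cohorts rare, which is inconsistent with an
  exact signed-rank $p < 0.001$ at $n = 12$ ever being observed; the
  shared factor keeps the marginals and restores the pairing.
* per-pool $T_1$s (tumour 16.6/22.1, muscle 15.9/21.1 ms bound/fluid), the
  two-pool agar tubes (bound fraction 0.88, $T_1$ 5/23.3 ms) and the
  inversion efficiency (1.0): solved numerically so the *noiseless* fast
  chain reproduces all four cohort means, followed by one shifted-target
  iteration absorbing the measured noisy-chain offsets. Modelling the agar
  as a gel-bound/free mixture is what lets the tube calibration carry the
  same saturation and arccos biases as tissue, so they cancel.
* noise sd 2.47 (arbitrary units): set so the cohort-mean tumour TSC image
  SNR is 82.2. The IWS SNR that follows (~42) is higher than the emulated
  study's 15, an accepted deviation: with a common noise level and the IWS
  means pinned, the IWS signal fraction is not free.
* cellularity link: cells per 1000 µm² $= \max(10 f_{ic} + \varepsilon,
  0.05)$, $\varepsilon \sim N(0, 0.45)$; the jitter was Monte-Carlo
  calibrated so the mean Spearman correlation between estimated tumour TSC
  and cellularity over 200 twelve-subject cohorts is −0.92.

Problem sizes in routine use: cohort statistics run on 64³ fast-mode
volumes restricted to a bounding box around the compartments plus the
background ROI (`cohortPlan`), identical to the full-array chain in the
noiseless limit and statistically identical otherwise; the cones chain is
run at 32³–64³ reconstructions.

# Histology

`makeHistologyImage` renders dark elliptical nuclei (semi-axes ~4.2×3 µm)
on a lighter tissue background, optionally with a slide-background margin
and a controlled fraction of touching pairs. Counting uses a robust
dark-object threshold (median − 6·MAD of tissue intensities — plain Otsu
fails when nuclei occupy a tiny or large fraction of the tissue), a
distance-transform watershed to split touching nuclei, and area gates of
20–400 µm². Tissue area comes from a two-threshold Otsu with an explicit
slide-presence test. All thresholds are relative, so counting is invariant
to global linear intensity rescaling. Cellularity is $N/A \times 1000$.

# Cohort statistics

Paired tumour–muscle comparisons follow a normality gate: Shapiro–Wilk on
the differences at 0.05 (config-exposed), paired *t* if not rejected,
otherwise Wilcoxon signed-rank. The signed-rank p-value is exact — full
enumeration of the $2^n$ sign patterns via the generating-function
recursion for $n \le 25$, extended to tied absolute differences through
doubled mid-ranks for $n \le 16$ — with a tie-corrected normal
approximation beyond. Zero differences are dropped and counted. Spearman's
rho is the Pearson correlation of mid-ranks with a two-sided *t*
approximation. All tests are two-sided.

# What the synthetic cohorts do and do not show

The phantom reproduces the quantitative structure of a surface-coil sodium
study — compartment concentrations, coil-field inhomogeneity with
reciprocity, Rician noise at matched SNR, tube calibration, and a
monotone cellularity link — so a passing suite demonstrates that the
correction and calibration chain recovers known truth through realistic
distortions. It does not demonstrate robustness to what the generator
omits: anatomically realistic geometry, motion and misregistration between
acquisitions (and the edge artefacts they cause), partial-volume mixing
beyond voxelization, multi-channel coils, trajectory imperfections, or
biexponential transverse decay. Agreement with the emulated cohort values
is by construction of the calibrated defaults; the informative content of
the acceptance checks is that the *pipeline's estimates*, under noise and
inhomogeneity, stay within a few percent of that construction.

# Numerical choices

Kaiser–Bessel shape parameter per the standard oversampling-2 choice;
deapodization by the discrete transform of the integer-sampled kernel
(scale-exact); periodic wraparound on the oversampled grid; reconstruction
normalised to unit point-spread-function peak, with absolute scale left to
the tube calibration. The arccos argument is clamped to $[-1, 1]$;
degenerate 0/0 ratios fall back to 1 and are excluded by the signal
threshold. Negative concentrations clamp to zero (counted); clamped
radicands in the noise-bias correction are counted likewise. Ties in the
signed-rank test use mid-ranks; zero differences are dropped. Seeds
propagate from one master seed per cohort to per-subject seeds, and every
random stage is reproducible from them.
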