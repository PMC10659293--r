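---
title: "Estimating the FSC and SSNR from a single measurement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the FSC and SSNR from a single measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sfsc)
```

## The statistical model

All estimators in this package are analyzed under a diagonal Gaussian
model.  A single measurement $y = x + \epsilon$ is observed on a
$d$-dimensional grid ($d \le 3$) with uniform voxel size $V$ in Angstrom.
The signal $x$ and noise $\epsilon$ are mean-zero Gaussian fields whose
unitary discrete Fourier coefficients are independent, with variances
$\lambda^2(r)$ and $\sigma^2(r)$ that are constant on radial shells
$S_r$.  The per-shell spectral signal-to-noise ratio is
$\mathrm{SSNR}(r) = \lambda^2(r)/\sigma^2(r)$, and the expected FSC of two
independent measurements of the same signal is

$$\mathrm{EFSC}(r) = \frac{\lambda^2(r)}{\lambda^2(r) + \sigma^2(r)},
  \qquad \mathrm{SSNR} = \frac{\mathrm{EFSC}}{1 - \mathrm{EFSC}}.$$

The package uses the unitary transform convention throughout
(`forward_transform` divides by $\sqrt{N^d}$), so Parseval's identity
holds exactly and "unit noise variance after whitening" is a statement
about individual Fourier coefficients.

## Shells and spectral profiles

`build_shells` labels each centered integer frequency $k$ with
$r = \mathrm{round}(\lVert k\rVert_2)$ and discards indices beyond the
inscribed Nyquist ball $\lVert k\rVert_2 > \min(\text{shape})/2$, where
shells are incomplete and anisotropic.  Shell $r$ sits at the physical
frequency $r/(\min(\text{shape})\,V)$ in 1/A.  `radial_power_spectrum`
reports the per-shell *mean* of $|\hat y[k]|^2$ (not the sum), so that
white noise of unit variance has a flat profile at 1; every consumer uses
the profile ratio-wise, so this choice only fixes a convenient scale.

Operations that must touch every coefficient (whitening, Wiener gains)
extend the shell lookup to the corners by clamping the label to the
outermost shell.

## The self FSC and its expectation

`split_even_odd` decimates the measurement along one axis into
$y_e[n] = y[2n]$ and $y_o[n] = y[2n+1]$.  The two members sample the same
underlying signal on lattices offset by one parent voxel, i.e. half a
downsampled voxel, which multiplies the odd member's Fourier coefficients
by a phase.  `phase_align` compensates it by multiplying
$\hat y_o[k]$ with $e^{-2\pi i k/N}$ ($k$ the centered signed frequency of
the downsampled grid, $N$ the parent length).  The sign follows from the
standard decimation identity

$$\hat y_o[k] = e^{2\pi i k/N}\,\bigl(\hat y[k] - \hat y[k + N/2]\bigr)/2,$$

which the test suite verifies against an $O(N^2)$ DFT-matrix oracle.  If
the alignment is skipped, the correlation of a noiseless radially
symmetric image equals the shell average of the residual phase
$\cos(2\pi k_a/N)$, which is a Bessel function $J_0(2\pi r/N)$ in 2-D; the
test suite asserts this law quantitatively.  Because the half-voxel phase
is bounded by $\pi/2$ over the decimated band, the misaligned curve decays
towards $J_0(\pi/2) \approx 0.47$ but cannot cross zero within the band —
the oscillation becomes visible as a strong, frequency-dependent
depression of the curve rather than a sign change.

`sfsc` computes the aligned FSC for each axis on the shells of the
downsampled grid and averages the per-axis curves with equal weights
(shells undefined on an axis are dropped from its mean and the summed
coefficient counts are recorded).  Under the model, each per-axis curve
estimates

$$\mathrm{ESFSC}[k] =
  \frac{\lambda^2[k] - \lambda^2[k'] + \sigma^2[k] - \sigma^2[k']}
       {\lambda^2[k] + \lambda^2[k'] + \sigma^2[k] + \sigma^2[k']},$$

with $k' = k + (N_a/2)e_a$ the aliasing partner.  Two conditions make this
a usable FSC estimate:

* **white noise**, so the $\sigma^2$ terms cancel in the numerator, and
* **rapid spectral decay**, so $\lambda^2[k'] \ll \lambda^2[k]$.

Then $\mathrm{ESFSC} \approx \lambda^2/(\lambda^2 + 2\sigma^2)$: the FSC
with the noise variance doubled.  `variance_correction` applies the exact
algebraic repair $c \mapsto 2c/(1+c)$ and flags the curve as corrected;
applying it twice is an error.  The checkerboard scheme
(`split_checkerboard`, retained as a comparison mode) decimates all axes
at once into the all-even and all-odd parity classes — the two classes
that admit a pure translation alignment — and inflates the noise variance
by $2^d$ instead of 2; the acceptance protocol fits both constants from
simulation.

### Interior shells

On the outermost quarter of the decimated band the aliasing partner
$\lVert k'\rVert$ falls inside the occupied band no matter how fast the
spectrum decays, so the rapid-decay reduction fails there *by
construction* while the exact expectation above remains accurate.
Quantitative FSC-scale comparisons (the noise-doubling fit, the condition
matrix, SSNR recovery) therefore use shells $1 \le r \le 0.75\,R$ of the
decimated band.  The full-band deviation is not an estimator defect and
disappears under the upsampling correction, which covers the complete
original band.

## Corrections

**Whitening.**  `whiten` divides each coefficient at shell $r$ by
$\sqrt{\sigma^2(r)}$; the transform is radial, hence the output is real,
the per-shell SSNR is exactly invariant, and noise drawn from the model
becomes white with unit coefficient variance.  A relative floor of
$10^{-12}$ of the profile maximum guards the division (with a warning).
Noise profiles come from `estimate_noise_sphere_complement` (voxels
inside a centered sphere zeroed; the masked power spectrum rescaled by
the inverse fraction of retained voxels, since masking removes that
fraction of the noise power), from `estimate_noise_slab` (power spectrum
of a signal-free slab, transferred to the parent shells by linear
interpolation in physical frequency; the slab's DC shell is excluded
because it reflects the region's mean offset, not spectral density), or
from `known_noise_model` when the truth is available.  Windowed slab
estimates inherit spectral leakage: when the noise spectrum spans several
decades across the band, the window sidelobes floor the tail estimate.
This is intrinsic to any periodogram of a restricted region; the test
suite therefore validates the slab estimator in a tomogram-like regime
(voxel size 4 A, B = 50 A^2) where the spectrum varies by a factor of a
few.

**Upsampling with noise subtraction.**  For slowly decaying (e.g.
whitened) spectra, `sfsc_upsampled` first upsamples by zero-padding in
Fourier space (`zero_pad_upsample`; per-axis Nyquist planes are split
half-and-half between the conjugate positions so the output stays real
and decimating back reproduces the input exactly).  Every aliasing
partner of the subsequent decimation then carries zero variance, and the
per-shell numerator reduces to $\lambda^2 + \sigma^2$ — biased upward by
exactly the known noise level.  Subtracting $n_r\gamma$ with
$\gamma = \sigma^2/4 = 1/4$ in whitened units makes the expectation equal
the EFSC, so the returned curve is already on the FSC scale.  The
bookkeeping deserves one line: upsampling by 2 scales unitary coefficient
variances by $2^d$ and decimation halves them, so the subtraction per
coefficient is $\gamma \cdot 2^{d+1} = 2^{d-1}$ in the units of the
decimated transforms.  A consequence worth knowing: after upsampling the
even and odd members are *identical* band-limited interpolants, so with
the subtraction disabled ($\gamma = 0$) the curve is 1 identically — all
of the estimator's information then flows through the subtraction, which
is why it only works when the noise level is genuinely known (i.e. after
whitening).

**Diagnostics.**  `diagnose` checks the spherically averaged power
spectrum: a flat upper half (coefficient of variation below 0.1 by
default) indicates white noise; a small low/high power ratio (below 10 by
default) indicates slow decay.  It recommends whitening and/or upsampling
accordingly.  The CV of a single draw scales like $\sqrt{2/n_r}$, so the
default threshold presumes shells of a few hundred coefficients —
appropriate for the volume sizes this tool targets; both thresholds are
arguments.

## Downstream consumers

`ssnr_from_fsc` inverts the EFSC relation per shell, clamping negative
correlations at zero and flagging values at 1 as infinite.
`resolution_at_threshold` scans from low to high frequency for the first
downward crossing of the threshold (default 1/7, i.e. SSNR 1/6),
interpolates linearly in frequency, and reports 1/frequency in Angstrom;
curves that never cross report the Nyquist resolution with a flag, and
curves already below threshold at the first shell are undefined.  The
first crossing (rather than the last) is standard practice and robust to
noisy curve tails.

`wiener_filter` multiplies each shell by the minimum mean-square-error
gain $\mathrm{SSNR}/(1+\mathrm{SSNR})$, which equals the expected FSC —
so the corrected SFSC *is* the gain.  Raw (uncorrected) SFSC curves are
refused, because using them double-counts the noise.  Gains are clamped
to $[0,1]$; the curve is mapped onto the measurement's shells by linear
interpolation in physical frequency, and shells beyond the curve's range
(including corner frequencies) receive zero gain.  An optional hard
low-pass at the 1/7-threshold resolution is exposed as a flag (default
off).  `lowpass` itself is strictly radial: at a cutoff equal to the
Nyquist resolution it removes only the corner frequencies beyond the
inscribed ball, so band-limited inputs pass unchanged.

## The generative module

`synthetic_spec` fixes the validation conditions: grids of even size,
voxel size 0.81 A, signal B-factor 100 A^2, white noise, and SNR 15 by
default — the reference imaging condition the estimators are validated
under; individual studies in the test suite vary B-factors, SNR and grid
size per protocol.  Amplitudes follow the crystallographic convention
$\exp(-B s^2/4)$ at spatial frequency $s$ in 1/A (the printed form of the
exponent in the source material is dimensionally ambiguous; this reading
makes B a conventional cryo-EM B-factor).  SNR is defined as the
real-space variance ratio $\mathrm{Var}(x)/\mathrm{Var}(\epsilon)$, the
common convention where none is stated.  Sampling shapes the unitary
transform of a white real Gaussian field by the per-shell amplitude,
which guarantees exact Hermitian symmetry and exactly shell-constant
variances; the DC component of both signal and noise is set to zero to
honor the mean-zero model.  The noise scale is chosen from expected
(population) variances, so the returned per-shell truth profiles are
exact.  `sample_measurement_pair` shares one signal draw between two
independent noise draws, providing the two-measurement FSC reference.
`phantom` is a deterministic scene of soft-edged spheres and a ring
confined to the central half of the box, for experiments that need a
compact, non-Gaussian signal (noise-region estimation, Wiener oracles).

What the generator does *not* emulate: contrast transfer functions,
projection geometry and missing wedges, non-stationary (spatially
varying) noise, and masking applied during reconstruction.  Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not robustness to those real-data effects; `diagnose` and the
flat-tail warning in the command-line tool surface the detectable
violations rather than modeling them.

## Expectation oracles

`esfsc_closed_form` evaluates the 1-D expectation formula on per-shell
profiles with partner label $N/2 - k$.  `esfsc_expected_grid` is the
honest $d$-dimensional oracle used by the Monte-Carlo tests: it
enumerates every coefficient of each decimated grid with its true
geometric aliasing partner and sums the per-shell moments.  Because the
SFSC is a ratio of shell sums, its expectation differs from the ratio of
expectations by a $O(1/n_r)$ term; the oracle therefore includes the
second-order delta-method correction, computable in closed form under the
Gaussian model (per-coefficient variances and covariances of the
numerator and the two denominators, doubled for conjugate-pair
duplication).  Without this term a 3-standard-error comparison on small
shells fails for purely finite-sample reasons.  Comparisons start at
shell 3 and, because hundreds of per-shell z-scores are examined
simultaneously, the tests require 90% of shells within 3 standard errors
and all within 4.5 — the false-alarm-controlled reading of a 3-sigma
criterion.

## Problem sizes and determinism

The validation protocols use $64^2$ images (500 simulated measurements
for the noise-inflation fits, 300 per profile for the oracle comparison,
100 per condition for the agreement matrix) and $32^3$ volumes (200 for
SSNR recovery, 100 for Wiener filtering) — sizes at which every protocol
completes in seconds while shell counts remain large enough for the
statistical tolerances.  All sampling functions seed R's generator from
`spec$seed`, so identical specifications give identical fields; the
command-line tool logs every seed it uses.

## Known limitations

* Uniform voxel sizes only; anisotropic sampling is not supported.
* Odd axis lengths are rejected rather than silently cropped (cropping
  changes the frequency axis; the caller must do it explicitly).
* The averaged SFSC curve is reported on the common (downsampled) band;
  per-axis curves retain their own ranges internally but are not exposed.
* Noise estimation from masked reconstructions is unreliable when masking
  altered the corner statistics; the flat-tail diagnostic warns but no
  remedy is attempted.
* Directional, conical and local resolution variants are out of scope.
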