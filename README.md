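# sfsc: self Fourier shell correlation

Estimate the Fourier shell correlation (FSC), spectral signal-to-noise
ratio (SSNR), global resolution and a data-driven Wiener filter **from a
single noisy measurement** — a 1-D signal, a 2-D image, or a 3-D volume
such as a cryo-EM half map or a cryo-ET tomogram.

The standard FSC needs two independent measurements of the same signal:

```
FSC(r) = Re <y1_hat, y2_hat>_r / (||y1_hat||_r ||y2_hat||_r)
```

computed over radial shells `S_r` in the Fourier domain, with the link
`SSNR(r) = FSC(r) / (1 - FSC(r))`.  When only one measurement `y = x + e`
is available, the *self* FSC (SFSC) decimates `y` into even- and
odd-indexed samples along one axis at a time, phase-aligns the odd member
(the two interleaved lattices are offset by half a downsampled voxel),
computes the FSC of each pair, and averages over axes.  Under a diagonal
Gaussian model with per-shell signal variance `lambda^2(r)` and noise
variance `sigma^2(r)`, the expectation of this estimator is

```
ESFSC[k] = (l2[k] - l2[k'] + s2[k] - s2[k']) / (l2[k] + l2[k'] + s2[k] + s2[k'])
```

where `k'` is the aliasing partner of `k`.  If the noise is white and the
signal spectrum decays fast, this reduces to `l2 / (l2 + 2 s2)` — the FSC
with the noise variance doubled — and the rescaling
`FSC = 2 SFSC / (1 + SFSC)` recovers the FSC scale.  When those
assumptions fail, the package provides the matching corrections:

* **whitening** (`estimate_noise_sphere_complement`, `estimate_noise_slab`,
  `whiten`) for colored noise;
* **Fourier upsampling with noise subtraction** (`sfsc_upsampled`) for
  slowly decaying spectra: zero-padding makes every aliasing partner carry
  zero variance, and the known (whitened) noise level `gamma = sigma^2/4`
  is subtracted from the correlation numerator, so the estimator targets
  the FSC scale directly;
* **diagnostics** (`diagnose`) that inspect the power-spectrum tail and
  recommend which corrections are needed.

Downstream: `resolution_at_threshold` (default threshold 1/7),
`ssnr_from_fsc`, `ssnr_direct`, and `wiener_filter` (shell gain
`SSNR/(1+SSNR)`, which equals the corrected SFSC).  A generative module
(`synthetic_spec`, `sample_measurement`, `phantom`) simulates Gaussian
random fields with B-factor spectral decay `exp(-B s^2 / 4)` so that every
estimator is testable against ground truth without external data.

## Worked example

A compact phantom image observed once under colored noise (B = 50 A^2,
SNR = 1, 64 x 64 px, 1 A/px):

```r
library(sfsc)

spec <- synthetic_spec(c(64, 64), base = "phantom", b_noise = 50, snr = 1,
                       voxel_size = 1, seed = 3)
m <- sample_measurement(spec)

d <- diagnose(m$y)
#> flat tail: FALSE   CV: 1.22   recommendation: whiten

nm <- estimate_noise_sphere_complement(m$y, radius = 16)  # A
yw <- whiten(m$y, nm)
curve <- sfsc_upsampled(yw)
head(as.data.frame(curve)[-1, c(1, 2, 3, 4)], 5)
#>   shell frequency_inv_angstrom resolution_angstrom value
#> 2     1                  0.016               64.00 0.985
#> 3     2                  0.031               32.00 0.872
#> 4     3                  0.047               21.33 0.445
#> 5     4                  0.062               16.00 0.350
#> 6     5                  0.078               12.80 0.162

resolution_at_threshold(curve, 1/7)$resolution_angstrom
#> 12.42  (flag "crossed")

wf <- wiener_filter(yw, curve)
den <- unwhiten(wf$filtered, nm)
mean((m$y$values - m$truth$x$values)^2)    #> 0.110   noisy input
mean((den$values  - m$truth$x$values)^2)   #> 0.0146  after Wiener filtering
```

The curve starts near 1 where the phantom dominates, crosses the 1/7
threshold at 12.4 A — the estimated resolution of this measurement — and
the SFSC-driven Wiener filter reduces the mean squared error against the
clean phantom by a factor of 7.5, with no tuning parameters.

The same pipeline runs from the shell (`inst/cli/sfsc`):

```sh
sfsc simulate --spec spec.json --out run/
sfsc sfsc run/measurement.mrc --whiten-sphere 16 --upsample --out run/
sfsc resolution run/measurement.mrc --whiten-sphere 16 --upsample
sfsc denoise tomogram.mrc --noise-slab 3:1:32 --out run/
```

Volumes are read and written as MRC/CCP4 (modes 0/1/2); curves as CSV and
JSON.

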