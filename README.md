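# sodiumpvc

Partial volume correction (PVC) for quantitative sodium (²³Na) MRI of
the Achilles tendon, with a fully synthetic evaluation bench.

Sodium MRI estimates the apparent tissue sodium content (aTSC, mM) of
the tendon, an early marker of tendinopathy. The measurement is
corrupted by two partial volume effects: the **tissue-fraction effect**
(coarse voxels average several tissues) and the **spill-over effect**
(the long-tailed point spread function of radial ultrashort-echo-time
acquisitions leaks signal between structures). This package is for
researchers developing or validating quantitative sodium pipelines: it
implements five corrections and the machinery to compare them against
a known ground truth.

## What is implemented

* **PSF simulation** for density-adapted 3D radial sampling: the
  k-space weighting `w(k) = [fs·e^(−(TE+t(k))/T2s*) +
  (1−fs)·e^(−(TE+t(k))/T2l*)]·a(k)` on the sampled ball, inverse
  transformed to a unit-gain kernel (`simulate_psf()`), with a
  Hanning reconstruction window and a two-regime trajectory model
  (gradient ramp, then density-adapted `k ∝ t^(1/3)`).
* **Digital tendon phantom** (`generate_phantom()`): parametric leg
  with skin, subcutaneous fat, muscle, calcaneus, retrocalcaneal
  bursa, vessels, a three-section tendon (INS/MID/MTJ, 30 mm each)
  with regional inhomogeneities, and four agarose reference rods; a
  forward corruption chain (`simulate_acquisition()`) applying
  relaxation weighting, block-mean downsampling, coil sensitivity,
  per-tissue PSF convolution and Rician noise, in that pinned order.
* **Corrections**:
  * `pssr_correct()` — region-level: `C = S_m − S_sur·(1−v_PS)/v_PS`;
  * `mlts_correct()` — voxel-level least-trimmed-squares unmixing of
    `y = Σᵢ fᵢ·Tᵢ` on 3×3×3 kernels (trimming 0.4);
  * `gtm_correct()` — geometric transfer matrix `W·T = m` with
    `W[i,j]` the mean of RSFⱼ over compartment i
    (RSF = mask ∗ PSF);
  * `stc_correct()` — iterative single target correction with
    cross-spill subtraction, recovery-factor division
    `R = Σᵢ mᵢ·(mᵢ ∗ PSFᵢ)`, nearest-minimal-positive-neighbor
    non-negativity, and period-2 steady-state detection;
  * `estc_correct()` — single-pass estimated STC using RSF-divided
    estimates repaired by an erode-and-fill operator.
* **Quantification** (`correct_and_quantify()`): PVC → coil
  sensitivity correction → reference-rod calibration
  (`signal = slope·conc + intercept`) → relaxation correction →
  aTSC maps and ROI statistics.
* **Monte Carlo evaluation** (`run_monte_carlo()`): method-by-method
  voxel-wise differences to ground truth across noise realizations.

## Worked example

Evaluate all methods on the synthetic phantom (96³ voxels at 1 mm,
acquired at 2 mm, MID SNR 10, 2 noise realizations for brevity):

```r
library(sodiumpvc)
report <- run_monte_carlo(evaluation_config(n_iterations = 2, snr = 10,
                                            seed = 42))
report
#> <evaluation_report>
#>
#> Noise-free mean voxel differences (mM):
#>  method mean_diff sd_vox rmse
#>    none     7.121   2.10 7.42
#>    pssr     4.868   2.19 5.34
#>    mlts     3.574   1.54 3.89
#>     gtm     1.463   1.72 2.26
#>     stc     0.735   1.30 1.49
#>    estc     0.565   1.32 1.44
#>
#> Monte Carlo combined differences (mM):
#>  method snr mean_diff sd_iter rmse
#>    estc  10     0.557  0.1397 2.88
#>     gtm  10     1.471  0.1439 2.90
#>    mlts  10     4.284  0.2207 4.63
#>    none  10     7.166  0.0891 7.81
#>    pssr  10     4.940  0.0891 5.80
#>     stc  10     0.727  0.1430 2.88
```

`mean_diff` is the voxel-wise aTSC error over the whole tendon
(positive = overestimation). Without correction the tendon is
overestimated by ~7 mM — mostly because the uncorrected reference
rods under-read (their spill-out shrinks the calibration slope, which
inflates every tissue). The tissue-fraction corrections (PSSR, mLTS)
remove the voxel-mixing part but not the spill-over and keep most of
the calibration inflation; the spill-over corrections (GTM, STC,
eSTC) recover the rods and the tendon, with the single-pass eSTC the
most accurate. The noise-free `sd_vox` column shows the voxel-wise
methods also preserve the regional concentration pattern best.

A thin CLI over the same functions is installed at
`inst/cli/sodiumpvc.R`:

```sh
Rscript inst/cli/sodiumpvc.R simulate-psf --t1 19.2 --t2l 14.2 \
    --t2s 1.4 --out psf.nii.gz
Rscript inst/cli/sodiumpvc.R evaluate --iterations 20 --snr 10 --seed 1 \
    --out report/
```

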