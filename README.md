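# ringalign

Template-free alignment and averaging of single-molecule localization
microscopy (SMLM/STORM) images of **semi-flexible ring-shaped
structures** — ciliary distal appendages, transition zones, centrioles,
nuclear-pore-like assemblies.

SMLM data are molecule lists: one (x, y, z) coordinate per detected
fluorophore, in nanometers.  Averaging many copies of a structure is the
standard way to beat under-labeling, but organelle-scale rings vary in
size and ellipticity from copy to copy, so rigid registration blurs the
average.  `ringalign` treats that flexibility as an explicit degree of
freedom:

1. **Circularize** — each structure's localizations are fitted to an
   ellipse by a robust (least-absolute-deviations) conic fit, radial
   outliers beyond 1.5 SD are trimmed, and the coordinates are deformed
   onto the cohort's average radius `R`:
   `x_circ = x/a * R`, `y_circ = y/b * R`.
2. **Register** — structures are rendered to pixel images and aligned by
   an exhaustive in-plane rotation search (0–359° in 1° steps) combined
   with subpixel translation from upsampled-DFT cross-correlation (1/100
   pixel), minimizing the normalized RMS error
   `E² = min_{α,x₀,y₀,θ} Σ|α·g_θ(x−x₀, y−y₀) − f|² / Σ|f|²`,
   equivalently maximizing the Fourier-domain cross-correlation.
3. **Iterate, template-free** — the first reference is the plain average
   of all images; each iteration re-registers every structure and
   averages again (10 iterations in 2D, 5 in 3D).  The final transforms
   are applied back to the coordinates, so the output is again a
   molecule list.
4. **3D** — flat structures tilted in space are handled by one extra
   exhaustive rotation about the x axis (no deformation), aligning x–y
   projections.
5. **Multicolor** — the reference channel is aligned and each
   structure's transform is transferred verbatim to its other channels.

Quality is quantified by Fourier ring correlation (1/7 threshold) of the
pooled aligned localizations and by the rotational autocorrelation of
the averaged image, whose peaks reveal N-fold symmetry.  A full
synthetic-data generator (`simulate_structures()`, `sim_preset()`)
reproduces the standard ring protocols with seeded randomness.

## Worked example

Align 20 simulated under-labeled rings (9 clusters on a 300 nm ring,
only 5 labeled per structure, 15 nm localization precision) and read the
ring symmetry off the averaged result:

```r
library(ringalign)

sims <- simulate_structures(sim_preset("ring9_underlabeled", seed = 1))
res  <- run_align2d(sims, deform = TRUE, n_iterations = 10,
                    pixel_size = 5, blur_sigma = 6)

round(res$R, 1)                      # cohort average radius, nm
round(res$run$mean_nrmse, 3)         # per-iteration mean NRMSE

pooled <- molecule_list(unlist(lapply(res$aligned, `[[`, "x")),
                        unlist(lapply(res$aligned, `[[`, "y")))
avg <- render_image(pooled, pixel_size = 5, field_size = 640,
                    blur_sigma = 5)
ac <- rotational_autocorrelation(avg)
head(ac$peaks)
```

```
> round(res$R, 1)
[1] 147.7
> round(res$run$mean_nrmse, 3)
 [1] 0.740 0.587 0.585 0.585 0.585 0.585 0.585 0.585 0.585 0.585
> head(ac$peaks)
  angle    height
1    41 0.7669876
4   160 0.6483646
2    81 0.6233407
3   120 0.6133132
> frc_resolution(pooled, seed = 1)
<frc_curve> resolution 15.6 nm (sd 0.9, threshold 0.143)
```

The fitted cohort radius is ~148 nm (truth: 150 nm), the mean NRMSE
drops and plateaus as the iterations converge, and the autocorrelation
of the averaged image peaks at the multiples of 40° — the ninefold
symmetry recovered from structures that individually show only five
clusters.  The last line is the Fourier-ring-correlation resolution of
the aligned pool (mean ± SD over 20 random half-splits at the 1/7
threshold); on semi-flexible (elliptical) cohorts it is finer with
deformation than without (`run_align2d(..., deform = FALSE)` gives the
rigid baseline).

A thin command-line front end wraps the same workflows:

```sh
Rscript inst/scripts/ringalign.R simulate --preset ring9_underlabeled --out sim/
Rscript inst/scripts/ringalign.R align2d --inputs 'sim/structure_*.csv' --out out/
Rscript inst/scripts/ringalign.R align3d --inputs 'sim/*.csv' --out out3d/ \
        --reference-channel 1
```

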