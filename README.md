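# petloop

Dynamic ¹⁸F-FDG PET analysis of the emotional-control loop — the bilateral
prefrontal cortex, striatum, hippocampus and thalamus — in generalized
anxiety disorder (GAD) and healthy controls.

In a dynamic FDG-PET protocol, each region's SUVmax (the hottest voxel's
standardized uptake value, Bq/cc) is sampled at 11 time points, every
15 minutes over 150 minutes, and standardized to the ipsilateral
cerebellum, a metabolically stable reference:

    SUVmax(standardized) = SUVmax(region) / SUVmax(same-side cerebellum)

Each standardized time-activity curve (TAC) is then summarised by three
metrics:

* **peak** — the maximum standardized SUVmax over the 11 points;
* **pre-peak uptake rate** — (peak − value at 0 min) / peak time;
* **post-peak metabolic rate** — (peak − value at 150 min) / (150 − peak time).

Groups are compared per region × metric with the pooled two-sample
Student t:

    t = (m₁ − m₂) / (s_p √(1/n₁ + 1/n₂)),
    s_p² = ((n₁−1)s₁² + (n₂−1)s₂²) / (n₁ + n₂ − 2),   df = n₁ + n₂ − 2

and the per-region pattern of significant differences is translated into
qualitative uptake-dynamics labels (slow-in / fast-in, slow-out / fast-out,
total decreased / increased).

The package also implements the image-analysis stages used around ROI
delineation in this kind of study, each usable on its own:

* **fusion** — linear intensity-hue-saturation transform plus a
  shift-invariant à-trous multiscale decomposition for PET/MRI slice
  fusion (low band from PET, max-|coefficient| detail from MRI);
* **saliency** — context-aware saliency: LAB patch dissimilarity
  D = d_color / (1 + c·d_position), per-patch saliency
  S = 1 − exp(−mean of the K smallest D), multiscale averaging and
  distance-to-focus context correction;
* **segmentation** — GrabCut: per-class K = 5 Gaussian mixtures in RGB,
  Gibbs energy E = U + V with contrast-adaptive boundary term
  V = γ Σ exp(−β‖z_m − z_n‖²), minimised by alternating mixture refits
  with exact graph min-cut, plus morphological boundary smoothing.

Because no per-subject data accompany the published tables, a synthetic
phantom module generates everything the pipeline consumes: 3D label maps,
4D dynamic volumes whose painted curves are recovered exactly by the
extraction code, cohorts of per-subject metrics drawn from the published
group summaries, and colour scenes with ground-truth masks for the image
stages.

## Worked example

The published group summaries (20 subjects per group) ship with the
package; reproducing the peak-uptake comparison table takes one call:

```r
library(petloop)
library(dplyr)

cmp <- compare_summaries()          # pooled t on every region x metric cell
tidy(cmp) |> filter(metric == "peak") |>
  select(roi, side, mean_healthy, mean_gad, t_abs, p, significant)
#>   roi         side  mean_healthy mean_gad t_abs        p significant
#> 1 prefrontal  left          2.41     2.04  5.71 1.44e- 6 TRUE
#> 2 prefrontal  right         2.52     2.06  6.86 3.84e- 8 TRUE
#> 3 striatum    left          1.95     1.41  9.47 1.51e-11 TRUE
#> 4 striatum    right         1.97     1.97  0    1   e+ 0 FALSE
#> 5 hippocampus left          1.65     1.16  8.77 1.16e-10 TRUE
#> 6 hippocampus right         1.63     1.63  0    1   e+ 0 FALSE
#> 7 thalamus    left          1.71     2.13  6.39 1.68e- 7 TRUE
#> 8 thalamus    right         1.69     2.08  6.98 2.65e- 8 TRUE
```

`t_abs` reproduces the published |t| to two decimals in 22 of the 24
cells; the two exceptions are right-side post-peak cells whose printed
t = 2.1 is not consistent with their own printed means and SDs (they
compute to 2.00). The qualitative dynamics labels follow directly:

```r
classify_dynamics(cmp)
#>   roi         side  in_label out_label total_label
#> 1 prefrontal  left  slow-in  fast-out  decreased
#> 2 prefrontal  right slow-in  fast-out  decreased
#> 3 striatum    left  slow-in  slow-out  decreased
#> 4 striatum    right none     none      none
#> 5 hippocampus left  slow-in  slow-out  decreased
#> 6 hippocampus right none     none      none
#> 7 thalamus    left  fast-in  fast-out  increased
#> 8 thalamus    right fast-in  none      increased
```

So in GAD, tracer enters the prefrontal cortex more slowly and leaves it
faster with a lower total, the left striatum and hippocampus slow down in
both directions with a lower total, and the thalamus speeds up with a
higher total — the right striatum and hippocampus show no difference.

An end-to-end simulated run (cohort simulation → metrics → tables →
labels → figures) is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1, n_subjects = 20), out_dir = "out")
res$dynamics          # labels recomputed from the simulated cohorts
```

and single stages are ordinary functions, e.g.
`injection_dose(60)` returns `6` (mCi) for a 60-kg subject, and

```r
lm  <- make_label_map(c(32, 32, 32))
vol <- render_dynamic_volume(dplyr::bind_cols(loop_rois(), random_tac_params(8, seed = 1)), lm)
cur <- extract_suvmax_curve(vol, lm, "prefrontal", "left")
uptake_metrics(normalize_to_cerebellum(cur, extract_suvmax_curve(vol, lm, "cerebellum", "left")))
```

recovers the generating peak and rates exactly on a noiseless phantom.

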