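# smlmpipe

Quantitative cluster analysis of single-molecule localization microscopy
(STORM) data, built for substrate-comparison studies of focal-adhesion
proteins: how does the nanoscale organization of an adapter protein such as
vinculin differ between cells grown on glass and on single-layer graphene?

The package covers the full chain from raw camera frames to two-condition
statistics:

1. **localize** — per-frame spot detection at a fixed counts/pixel threshold
   and integrated 2D Gaussian fitting of each single-molecule image, giving a
   localization table (one row per blinking event) with x–y position, photon
   count, PSF width and background.
2. **drift** — stage-drift estimation by cross-correlating super-resolution
   images reconstructed from temporal subsets of frames, with sub-bin peak
   interpolation and per-frame correction.
3. **cluster** — the distance-based segmentation at the core of the analysis:
   localizations are binned into 20 nm pixels, filtered with a 7 × 7 square
   kernel into a density map, binarized at a constant threshold, and the
   connected candidate regions are split into clusters by local-maxima-seeded
   iterative centroid refinement on the raw coordinates. Clusters below a
   minimum molecule count are discarded; a scale factor sets the minimum seed
   separation and with it the degree of segmentation.
4. **quantify** — per-condition summaries (mean ± SEM of N_loc/cluster,
   cluster area in nm², density N_loc/nm², clusters/μm²), percent changes
   against a reference condition, two-sample Kolmogorov–Smirnov tests on the
   per-cluster distributions and an unpaired two-tailed Student's t-test on
   per-field cluster densities (significance at p < 0.05).
5. **photophysics** — blinking controls: the temporal decay of the event rate
   is fitted with A·exp(−k·t) + c to estimate the effective OFF-switching
   rate k_OFF, and photons-per-event statistics verify that the substrate
   leaves the fluorophore photocycle unchanged.
6. **simulate** — a fully ground-truthed synthetic STORM generator (clustered
   emitter fields, two-state ON/OFF blinking with an activation cycle of 1
   activation + 3 readout frames, integrated-Gaussian PSF rendering with
   Poisson/EMCCD/read noise, rigid stage drift, and a DNA-origami-like
   calibration standard with 86 labeling sites per structure), so every
   analysis stage can be validated against known truth.

## Worked example

Two synthetic acquisitions whose generative events-per-cluster means are 54
(glass) and 92.5 (graphene) — everything else identical — segmented with one
shared configuration and compared:

```r
library(smlmpipe)

make_condition <- function(events_per_cluster, seed) {
  params <- scene_params(roi_width_nm = 10000, roi_height_nm = 10000,
                         cluster_rate = 6,
                         molecules_per_cluster_mean = events_per_cluster,
                         cluster_sigma_nm = 12, background_molecule_rate = 5,
                         min_center_sep_nm = 250)
  scene <- generate_scene(params, seed = seed)
  scene <- simulate_blinking(scene,
                             blink_model(k_on = 0, k_off = 1,
                                         initial_on_fraction = 1,
                                         activation_boost = 1),
                             camera_model(frame_count = 4), seed = seed + 1)
  ground_truth_table(scene, precision_nm = 10, seed = seed + 2)
}
glass    <- make_condition(54.0, seed = 300)
graphene <- make_condition(92.5, seed = 400)

config <- cluster_config()   # 20 nm bins, 7x7 kernel, threshold 8
compare_conditions(list(cluster_field(glass, config)),
                   list(cluster_field(graphene, config)),
                   labels = c("glass", "graphene"))
#> comparison_report: graphene vs glass
#>   N_loc/cluster    +71% (exact +71.05%), p = 0 *
#>   cluster area     +21% (exact +20.61%), p = 0 *
#>   cluster density  +41% (exact +40.89%), p = 0 *
#>   clusters/um^2    -10% (exact -10.24%), p = NA
```

The +71% enrichment in localizations per cluster is the configured ratio
(92.5/54), recovered end to end through segmentation and quantification; the
KS test on the per-cluster distributions is significant (the star marks
p < 0.05; clusters/μm² has no t-test p-value with a single field per
condition). A blinking control on a simulated acquisition with k_OFF = 0.02
per frame recovers the rate from the event-rate decay:

```r
scene <- generate_scene(scene_params(roi_width_nm = 10000, roi_height_nm = 10000,
                                     cluster_rate = 0,
                                     background_molecule_rate = 30), seed = 500)
scene <- simulate_blinking(scene,
                           blink_model(k_on = 5e-5, k_off = 0.02,
                                       initial_on_fraction = 1,
                                       activation_boost = 1),
                           camera_model(frame_count = 2500), seed = 501)
trace <- event_rate_trace(ground_truth_table(scene, seed = 502), bin_frames = 10)
fit_off_rate(trace, frame_rate_hz = 33)
#> rate_fit: k_off = 0.01997 /frame (0.659 /s), A = 28538.9, offset = 0.0
```

A ready-made two-condition pipeline run (simulation → drift correction →
clustering → comparison, all outputs on disk) is:

```sh
Rscript inst/cli/smlmpipe.R run --config inst/extdata/demo_config.yaml \
    --out runs/demo --seed 5
```

or `run_pipeline("inst/extdata/demo_config.yaml", out = "runs/demo", seed = 5)`
from R. Real localization tables are read with `read_localizations()`, which
understands the native CSV dialect plus ThunderSTORM- and Picasso-style
exports.

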