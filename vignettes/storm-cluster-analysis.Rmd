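---
title: "Models and design of the smlmpipe STORM cluster analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the smlmpipe STORM cluster analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmpipe)
```

# Scope

`smlmpipe` quantifies the nanoscale clustering of a labeled protein from
STORM acquisitions and compares two substrate conditions. The counting
currency throughout is the *localization event*: one fitted position of one
blinking emission in one frame. Events are deliberately never linked or
grouped into molecules — per-cluster event counts (N_loc/cluster) are the
comparison metric, and any molecule-grouping step would change that currency
and silently rescale every downstream number. Absolute molecular copy
numbers are therefore out of scope; ratios and distributions between
conditions analyzed with identical settings are the meaningful output.

# The forward model (simulate)

The synthetic generator exists so that every analysis stage can be validated
against known ground truth.

**Spatial field.** Cluster centers follow a homogeneous Poisson process with
intensity `cluster_rate` (clusters/μm²). Per-cluster molecule counts are
Poisson truncated at ≥ 1 — the minimal distribution compatible with an
empirical mean, and configurable; molecules scatter isotropically
(σ = `cluster_sigma_nm`) about their center. Stray background molecules are
uniform. The defaults (10 clusters/μm², 54 molecules/cluster, σ = 12 nm,
5 background molecules/μm²) were fixed once to mirror the focal-adhesion
regime the analysis targets: tens of events per cluster, cluster areas of a
few hundred nm², densities of order 0.1 events/nm². An optional hard-core
minimum center separation (`min_center_sep_nm`, sequential inhibition,
default off) supports benchmarks that require unambiguous,
non-overlapping ground-truth clusters; the pure Poisson process remains the
default because real fields do overlap.

The `origami_grid` scene type lays out DNA-origami-like calibration
standards on a jittered grid, each with exactly 86 labeling sites spread
over a ~100 nm footprint — the standard used to check that localization
yields are substrate-independent.

**Blinking.** Each molecule is a two-state ON/OFF Markov chain advanced once
per frame; `k_on` and `k_off` are per-frame switching probabilities, so ON
dwells are geometric with mean 1/`k_off` frames. Every
`activation_period`-th frame (default 4, the 1-activation + 3-readout
imaging cycle) multiplies `k_on` by `activation_boost`, modeling the
activator-dye pulse. Each ON frame emits one event with Poisson photons.
Labeling stoichiometry (multiple dyes per antibody) is collapsed into
re-activation kinetics: what matters downstream is the event stream, and a
separate epitope model would add parameters the analysis cannot identify.

**Camera.** Events are rendered as *integrated* Gaussian PSFs — per-pixel
mass from the Gaussian CDF over the half-open pixel, not a point sample —
because point-sampled PSFs bias sub-pixel fitting tests at exactly the
precision this package needs to measure. Pixel counts are Poisson-sampled,
multiplied by the EM gain, and offset by baseline plus Gaussian read noise.
EMCCD excess noise is omitted (the gain is a deterministic multiplier): it
would inflate all variances by a common factor ~2 without affecting any
ratio or recovery property the package asserts. Acquisition defaults follow
the standard protocol: 20,000 frames at 33 Hz, 30 ms exposure, 160 nm
pixels.

`ground_truth_table()` shortcuts the camera: it converts emission events
directly into a localization table with a configurable Gaussian localization
error (default 10 nm) and optional injected drift. Recovery benchmarks for
drift, clustering, quantification and kinetics run on this table so that
they measure the stage under test, not the localizer.

# Localization

Spots are strict 8-neighborhood local maxima exceeding the per-frame median
by a fixed `threshold_counts` — referencing the median keeps "the same
threshold" meaningful under baseline drift while remaining one constant
across all frames and conditions. Near-coincident candidates merge to the
brighter peak.

Each candidate is fitted with the integrated 2D Gaussian (center, integrated
signal, width, flat background) in a 7 × 7 pixel window. The default fit is
**shot-noise-weighted least squares**: residuals are scaled by the
camera-model count variance (`em_gain × model + read_noise²`). Plain
unweighted least squares is available (`method = "ls"`) but is not the
default because it measurably inflates localization scatter: on the
package's own 500-spot benchmark, unweighted LS sits ~39% above the
σ_PSF/√N precision bound while the weighted fit sits ~9% above (the residual
excess being pixelation and the fitted background). Fits are rejected —
never raised as errors — on non-convergence, centers off the candidate by
more than 2 px, non-positive signal, or widths outside [0.5, 2.5] × the
nominal PSF width; the width gate removes overlapping-emitter and defocus
artifacts.

# Drift correction

The acquisition is split into `n_subsets` (default 10) equal frame ranges;
each subset is reconstructed as a 2D histogram at `recon_bin_nm` (default
20 nm, matching the analysis pixel), and displacements relative to the first
subset are the argmax of the FFT cross-correlation, refined to sub-bin
precision by three-point parabolic interpolation. The per-frame trajectory
interpolates linearly between subset midpoints and **extrapolates the end
segments linearly**. Constant end extrapolation was considered and rejected:
subset midpoints span only (n−1)/n of the acquisition, so constant ends
systematically truncate a linear drift by one subset's worth of motion
(50 nm of a 500 nm drift at 10 subsets) — a guaranteed bias larger than the
method's statistical error. Linear extrapolation recovers linear drift
exactly and degrades gracefully for random-walk drift, where the end
segments are short.

# Cluster segmentation

The segmentation follows the distance-based, density-seeded design:

1. **Binning** at `bin_nm` = 20 nm (half-open bins; the image sum equals the
   table size).
2. **Density map**: an *unnormalized* 7 × 7 moving-window sum, so the map is
   in localization counts per window and the constant threshold has
   interpretable units.
3. **Binarization** at `density_threshold` (strict `>`). The default, 8
   counts/window, is calibrated from a false-positive budget: a Poisson
   background of 50 localizations/μm² gives 0.98 expected counts per window,
   and P(X > 8) ≈ 9.6 × 10⁻⁷ keeps false candidate regions below one per
   100 μm². The mask only *locates* candidate regions; all subsequent
   computation uses raw coordinates.
4. **Connected components**: 8-connectivity by default, 4 available. (The
   "six-connected" phrasing in the source literature is 3D voxel
   terminology; in 2D the choice is 4 vs 8, and 8 is the permissive reading
   that avoids splitting diagonal bridges.) Labeling is done in-package
   because the available image library supports only 4-connectivity; it is
   cross-checked against that library and against a brute-force flood fill
   in the tests.
5. **Seeding**: strict local maxima of the density map within the region
   (plateaus of equal value contribute a single seed at their centroid —
   point-symmetric clusters genuinely produce flat-topped density maps).
   Seeds closer than `scale_factor × bin_nm` merge to their density-weighted
   mean; the scale factor (default 5, i.e. 100 nm) is the single knob for
   segmentation degree and does not otherwise affect clustering.
6. **Refinement**: Lloyd-style nearest-centroid iteration on raw
   localizations (ties to the lowest index), stopping when the relative
   change of the summed squared distances falls below `convergence_tol`
   (10⁻⁶) or after `max_iterations` (100). On well-separated two-blob
   instances this provably reaches the exhaustive 2-means optimum, which the
   tests verify by enumeration.
7. **Filtering**: clusters with fewer than `min_molecules` (default 3)
   localizations are dropped as noise.

**Area** is the convex hull of member localizations (shoelace formula), with
an occupied-bins × 400 nm² fallback for degenerate (collinear or < 3-point)
clusters, and a pure bins method as a config option — the hull is the
default because it is parameter-free at the raw-coordinate level, but
neither convention is canonical and published areas at these densities are
compatible with both. **Density** is N_loc/area. **Clusters/μm²** needs a
normalization region that raw data do not define; the default reference area
is the morphological closing (3 × 3 structuring element) of the binary-mask
support — a labeled-footprint proxy — and is echoed in every output so a
user-supplied ROI can override it.

A note on threshold monotonicity: raising the density threshold always
*shrinks* the candidate mask (supports are nested), but it can transiently
*increase* the number of connected regions by splitting one region into
several before they vanish. Raising `min_molecules` or `scale_factor` never
increases the cluster count.

# Quantification and statistics

Distribution metrics (N_loc/cluster, area, density) pool clusters across
fields; clusters/μm² is computed per field and averaged. Percent change is
100·(test − reference)/reference, reported exactly and rounded half away
from zero (the convention of the printed integer percentages this package
reproduces). Distributions are compared with the two-sample KS test using
the asymptotic p-value — per-cluster sample sizes here are hundreds to tens
of thousands, squarely in the asymptotic regime, with the exact option
available for small samples. Per-field cluster densities use the
pooled-variance unpaired two-tailed Student's t-test; degenerate
zero-variance inputs short-circuit (equal means → p = 1, unequal → p = 0
with a flag) rather than erroring. No multiple-testing correction is
applied, matching the source analysis. Significance is declared at p < 0.05.

# Photophysics controls

The event-rate trace (events per `bin_frames`) is the table-level proxy for
ensemble fluorescence decay. Its initial decay — from the global maximum bin
to the first bin within 10% of the tail plateau — is fitted with
N(t) = A·e^(−kt) + c by Poisson-weighted nonlinear least squares; the offset
absorbs steady-state re-activation. With molecules starting ON and weak
re-activation, the ensemble decay constant is −log(1 − k_on − k_off) ≈
k_off + k_on, so k is reported as the effective OFF rate (per frame and,
via the frame rate, per second).

The fit's raw standard error assumes independent bins, but neighboring bins
count the *same* ON molecules: counts decorrelate over one mean ON dwell
(1/k frames). The reported effective standard error (`k_stderr_eff`, and the
`k_ci95` interval built from it) is therefore inflated by
√(dwell/bin width). Empirically this matches the across-replicate scatter
almost exactly, while the uncorrected SE understates it by the same factor —
the corrected interval is what the substrate-equivalence check uses, and
with honest intervals two identical-kinetics acquisitions overlap in ≈ 99%
of replicates.

Origami calibration acquisitions are compared structure-wise: each structure
segments into one cluster, and the per-structure event-count distributions
are KS-tested between substrates.

# Numerical and degenerate-input choices

* Coordinates are continuous nm, origin at the ROI top-left; pixel/bin p
  covers [p·size, (p+1)·size). All writers round coordinates at 0.01 nm.
* Cross-correlation uses zero-padded FFTs (no circular wrap) and clamps the
  parabolic sub-bin refinement to ±0.5 bin.
* Empty inputs return empty, typed results (empty table → empty cluster
  set, all-zero trace) except where a result would be meaningless, which
  raises a classed error (`smlmpipe_estimation_error`, `smlmpipe_fit_error`,
  `smlmpipe_format_error`, ...).
* Ties in centroid assignment go to the lowest cluster index; empty clusters
  are dropped after refinement.
* All stochastic stages take explicit seeds and restore the caller's RNG
  state; identical seeds give bit-identical outputs.

# What the synthetic tests do and do not show

The generator reproduces the statistical structure the analysis relies on —
clustered point fields, geometric blinking, shot-noise-limited imaging,
rigid drift — so passing tests demonstrate that the pipeline recovers known
parameters under its own model assumptions at realistic problem sizes
(10 × 10 μm fields with ~600 clusters and ~90,000 events for the
two-condition benchmark; 10,000-frame drift runs with ~75,000 events;
~160,000-event kinetics runs; 500-spot precision batches). They do not
demonstrate robustness to what the generator omits: non-Gaussian PSF
aberrations, sCMOS-style pixel-dependent noise, EMCCD excess noise,
non-rigid (thermal-gradient) drift, repeated-antibody label clustering, or
true molecular copy-number inference from events. Claims on real data should
lean on the relative, identically-parameterized comparison design, which
cancels most of these systematics between conditions.

# Known limitations

* Single-emitter fitting only: overlapping emitters closer than ~the PSF
  width merge into one event (the sparse-regime assumption of STORM).
* 2D only; no astigmatism or z-localization.
* The exponential decay model treats the trace as one global pool; strongly
  heterogeneous fields (mixed dye environments) would need multi-component
  fits.
* Blinking-induced overcounting is inherent to the event currency: stray
  single molecules that blink repeatedly are legitimately segmented as small
  clusters if they clear the density threshold, exactly as in the real
  analysis; the minimum-molecule filter is the only guard.
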