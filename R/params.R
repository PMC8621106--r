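#' Scene parameters for the synthetic emitter-field generator
#'
#' Describes the spatial statistics of a simulated field of labeled molecules:
#' cluster centers follow a homogeneous Poisson process at `cluster_rate`,
#' per-cluster molecule counts are Poisson (truncated at >= 1) with mean
#' `molecules_per_cluster_mean`, molecules scatter isotropically about their
#' center with standard deviation `cluster_sigma_nm`, and stray background
#' molecules are uniform at `background_molecule_rate`. The `origami_grid`
#' scene type instead lays out a grid of DNA-origami-like calibration
#' standards, each carrying exactly `origami_sites` labeling sites.
#'
#' @param roi_width_nm,roi_height_nm field of view in nm.
#' @param cluster_rate clusters per square micrometer.
#' @param molecules_per_cluster_mean mean molecules per cluster (>= 1).
#' @param cluster_sigma_nm isotropic spread of molecules about the cluster
#'   center, in nm.
#' @param background_molecule_rate stray (unclustered) molecules per square
#'   micrometer.
#' @param scene_type `"clustered"` or `"origami_grid"`.
#' @param origami_sites labeling sites per origami structure (default 86, the
#'   calibration standard's handle count).
#' @param origami_structures number of origami structures in an
#'   `origami_grid` scene.
#' @param origami_size_nm side of the square footprint over which origami
#'   sites are placed.
#' @param min_center_sep_nm optional hard-core minimum separation between
#'   cluster centers (0 = pure Poisson process); positive values apply
#'   sequential-inhibition thinning and are intended for constructing
#'   well-separated benchmark fields.
#' @param seed RNG seed attached to the scene (used by [generate_scene()]).
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(roi_width_nm = 10000, roi_height_nm = 10000,
                         cluster_rate = 10, molecules_per_cluster_mean = 54,
                         cluster_sigma_nm = 12, background_molecule_rate = 5,
                         scene_type = c("clustered", "origami_grid"),
                         origami_sites = 86, origami_structures = 16,
                         origami_size_nm = 100,
                         min_center_sep_nm = 0, seed = NULL) {
  scene_type <- match.arg(scene_type)
  check_scalar(roi_width_nm, "roi_width_nm", 0, strict = TRUE)
  check_scalar(roi_height_nm, "roi_height_nm", 0, strict = TRUE)
  check_scalar(cluster_rate, "cluster_rate", 0)
  check_scalar(background_molecule_rate, "background_molecule_rate", 0)
  check_scalar(cluster_sigma_nm, "cluster_sigma_nm", 0)
  check_scalar(min_center_sep_nm, "min_center_sep_nm", 0)
  if (scene_type == "clustered") {
    check_scalar(molecules_per_cluster_mean, "molecules_per_cluster_mean", 1)
  }
  check_scalar(origami_sites, "origami_sites", 1)
  check_scalar(origami_structures, "origami_structures", 0)
  structure(list(
    roi_width_nm = roi_width_nm, roi_height_nm = roi_height_nm,
    cluster_rate = cluster_rate,
    molecules_per_cluster_mean = molecules_per_cluster_mean,
    cluster_sigma_nm = cluster_sigma_nm,
    background_molecule_rate = background_molecule_rate,
    scene_type = scene_type, origami_sites = as.integer(origami_sites),
    origami_structures = as.integer(origami_structures),
    origami_size_nm = origami_size_nm,
    min_center_sep_nm = min_center_sep_nm, seed = seed
  ), class = "scene_params")
}

#' Two-state blinking kinetics
#'
#' Each molecule is a two-state (ON/OFF) Markov chain advanced once per frame.
#' `k_on` and `k_off` are per-frame switching probabilities (clamped to
#' \[0, 1\]); ON dwell times are therefore geometric with mean `1/k_off`
#' frames. Every `activation_period`-th frame models the activation pulse of
#' an activator-reporter imaging cycle: `k_on` is multiplied by
#' `activation_boost` on those frames. The default period of 4 corresponds to
#' 1 activation frame followed by 3 readout frames.
#'
#' @param k_on per-frame OFF->ON switching probability.
#' @param k_off per-frame ON->OFF switching probability.
#' @param activation_period activation cycle length in frames (>= 1).
#' @param activation_boost multiplier on `k_on` during activation frames.
#' @param mean_photons_per_frame mean detected photons emitted per ON frame.
#' @param initial_on_fraction probability a molecule starts in the ON state.
#' @return an object of class `blink_model`.
#' @export
blink_model <- function(k_on = 2e-4, k_off = 0.5, activation_period = 4,
                        activation_boost = 10, mean_photons_per_frame = 1000,
                        initial_on_fraction = 0.5) {
  check_scalar(k_on, "k_on", 0)
  check_scalar(k_off, "k_off", 0)
  check_scalar(activation_period, "activation_period", 1)
  check_scalar(activation_boost, "activation_boost", 0)
  check_scalar(mean_photons_per_frame, "mean_photons_per_frame", 0, strict = TRUE)
  check_scalar(initial_on_fraction, "initial_on_fraction", 0)
  if (initial_on_fraction > 1) stop_invalid("initial_on_fraction must be <= 1")
  structure(list(
    k_on = k_on, k_off = k_off,
    activation_period = as.integer(activation_period),
    activation_boost = activation_boost,
    mean_photons_per_frame = mean_photons_per_frame,
    initial_on_fraction = initial_on_fraction
  ), class = "blink_model")
}

#' EMCCD camera and acquisition model
#'
#' @param pixel_size_nm back-projected camera pixel size (default 160 nm).
#' @param psf_sigma_nm standard deviation of the Gaussian PSF, in nm.
#' @param em_gain electron-multiplying gain (counts per photon); applied as a
#'   deterministic multiplier.
#' @param read_noise RMS read noise in counts.
#' @param baseline camera count offset.
#' @param frame_count frames per acquisition (default 20,000).
#' @param exposure_ms exposure time per frame (default 30 ms, i.e. a 33 Hz
#'   frame rate).
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(pixel_size_nm = 160, psf_sigma_nm = 150, em_gain = 10,
                         read_noise = 2, baseline = 100, frame_count = 20000,
                         exposure_ms = 30) {
  check_scalar(pixel_size_nm, "pixel_size_nm", 0, strict = TRUE)
  check_scalar(psf_sigma_nm, "psf_sigma_nm", 0, strict = TRUE)
  check_scalar(em_gain, "em_gain", 0, strict = TRUE)
  check_scalar(read_noise, "read_noise", 0)
  check_scalar(baseline, "baseline", 0)
  check_scalar(frame_count, "frame_count", 1)
  check_scalar(exposure_ms, "exposure_ms", 0, strict = TRUE)
  structure(list(
    pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
    em_gain = em_gain, read_noise = read_noise, baseline = baseline,
    frame_count = as.integer(frame_count), exposure_ms = exposure_ms
  ), class = "camera_model")
}

#' Configuration of the distance-based cluster segmentation
#'
#' Localizations are binned at `bin_nm` (20 nm analysis pixels), the binned
#' image is filtered with an unnormalized square sum kernel of `kernel_px` x
#' `kernel_px` bins to form a density map, the map is binarized at a constant
#' `density_threshold` (strict `>`, in localization counts per window), and
#' connected components of the mask delimit candidate regions. Within each
#' region, density-map local maxima seed an iterative nearest-centroid
#' refinement of the raw localization coordinates; seeds closer than
#' `scale_factor * bin_nm` are merged first, so `scale_factor` sets the
#' degree of segmentation. Clusters with fewer than `min_molecules`
#' localizations are discarded as noise.
#'
#' @param bin_nm analysis pixel (bin) size in nm; default 20.
#' @param kernel_px odd side of the square density kernel; default 7.
#' @param density_threshold constant threshold on the density map, in
#'   localizations per kernel window. The default (8) keeps false regions
#'   below 1 per 100 square micrometers for a Poisson background of 50
#'   localizations per square micrometer.
#' @param connectivity pixel adjacency for connected components, 4 or 8.
#' @param scale_factor minimum seed separation in units of `bin_nm`.
#' @param min_molecules minimum localizations for a cluster to be kept.
#' @param max_iterations cap on centroid-refinement iterations.
#' @param convergence_tol relative change of the sum of squared distances at
#'   which refinement stops.
#' @param area_method `"hull"` (convex hull of member localizations, with a
#'   bin-count fallback for degenerate clusters) or `"bins"` (occupied
#'   `bin_nm` bins times the bin area).
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(bin_nm = 20, kernel_px = 7, density_threshold = 8,
                           connectivity = 8, scale_factor = 5,
                           min_molecules = 3, max_iterations = 100,
                           convergence_tol = 1e-6,
                           area_method = c("hull", "bins")) {
  area_method <- match.arg(area_method)
  check_scalar(bin_nm, "bin_nm", 0, strict = TRUE)
  check_scalar(kernel_px, "kernel_px", 1)
  if (kernel_px %% 2 == 0) stop_invalid("kernel_px must be odd")
  check_scalar(density_threshold, "density_threshold", 0)
  if (!connectivity %in% c(4, 8)) stop_invalid("connectivity must be 4 or 8")
  check_scalar(scale_factor, "scale_factor", 0)
  check_scalar(min_molecules, "min_molecules", 1)
  check_scalar(max_iterations, "max_iterations", 1)
  if (!(convergence_tol > 0 && convergence_tol < 1)) {
    stop_invalid("convergence_tol must be in (0, 1)")
  }
  structure(list(
    bin_nm = bin_nm, kernel_px = as.integer(kernel_px),
    density_threshold = density_threshold,
    connectivity = as.integer(connectivity), scale_factor = scale_factor,
    min_molecules = as.integer(min_molecules),
    max_iterations = as.integer(max_iterations),
    convergence_tol = convergence_tol, area_method = area_method
  ), class = "cluster_config")
}
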