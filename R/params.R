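#' Population parameters for the synthetic labelling experiment
#'
#' Describes a cell population after a nucleoside-analogue labelling pulse as
#' a two-component mixture: a replicating (S-phase) component whose nuclei
#' carry specific replication signal, and a non-replicating component whose
#' nuclei show only background. Signal magnitudes are arbitrary fluorescence
#' units (a.u.).
#'
#' The labelled fraction defaults to 0.44, the fraction of nuclei with a
#' clear replication signal after a 30-minute pulse in a typical cycling
#' human line.
#'
#' @param n_cells Number of cells in the population.
#' @param frac_replicating Fraction of cells in S phase, in (0, 1).
#' @param mu_signal_R Mean nuclear replication-channel signal of S-phase
#'   cells (a.u.).
#' @param mu_signal_nonR Mean background nuclear signal of non-S cells
#'   (a.u.). Must not exceed `mu_signal_R`.
#' @param cv_R,cv_nonR Coefficients of variation of the two signal
#'   components (dimensionless, >= 0).
#' @param seed Integer seed; identical seeds give identical populations.
#' @return An object of class `population_params`.
#' @seealso [generate_population()]
#' @export
population_params <- function(n_cells = 10000, frac_replicating = 0.44,
                              mu_signal_R = 2000, mu_signal_nonR = 100,
                              cv_R = 0.3, cv_nonR = 0.1, seed = NULL) {
  stopifnot(n_cells >= 0, is.numeric(frac_replicating))
  if (frac_replicating < 0 || frac_replicating >= 1)
    stop("frac_replicating must lie in [0, 1); got ", frac_replicating)
  if (!(mu_signal_R >= mu_signal_nonR) || mu_signal_nonR <= 0)
    stop("require mu_signal_R >= mu_signal_nonR > 0")
  if (cv_R < 0 || cv_nonR < 0) stop("coefficients of variation must be >= 0")
  structure(list(n_cells = as.integer(n_cells),
                 frac_replicating = frac_replicating,
                 mu_signal_R = mu_signal_R, mu_signal_nonR = mu_signal_nonR,
                 cv_R = cv_R, cv_nonR = cv_nonR, seed = seed),
            class = "population_params")
}

#' Cell-cycle structure of the synthetic population
#'
#' Phase fractions and DNA-content scale for the generator. The G2/M DNA
#' content is fixed at twice the G1 (2N) content; S-phase cells fall between
#' the two. `frac_s` must equal `frac_replicating` of the paired
#' [population_params()] because only S-phase cells incorporate the analogue.
#'
#' @param frac_g1,frac_s,frac_g2m Phase fractions; must sum to 1.
#' @param dna_g1 DNA-content units (a.u.) assigned to the 2N (G1) state.
#' @param dna_cv Coefficient of variation of the DNA-content measurement.
#' @return An object of class `cell_cycle_params` (with derived `dna_g2m =
#'   2 * dna_g1`).
#' @export
cell_cycle_params <- function(frac_g1 = 0.45, frac_s = 0.44, frac_g2m = 0.11,
                              dna_g1 = 100, dna_cv = 0.05) {
  total <- frac_g1 + frac_s + frac_g2m
  if (abs(total - 1) > 1e-9)
    stop("phase fractions must sum to 1 (got ", format(total, digits = 12), ")")
  if (any(c(frac_g1, frac_s, frac_g2m) < 0)) stop("phase fractions must be >= 0")
  stopifnot(dna_g1 > 0, dna_cv >= 0)
  structure(list(frac_g1 = frac_g1, frac_s = frac_s, frac_g2m = frac_g2m,
                 dna_g1 = dna_g1, dna_g2m = 2 * dna_g1, dna_cv = dna_cv),
            class = "cell_cycle_params")
}

#' Imaging parameters for synthetic two-channel microscopy
#'
#' Controls rendering of the DAPI and replication-signal channels. Nuclei are
#' drawn as non-overlapping disks; `min_center_spacing` is the minimum gap
#' (pixels) left between disk perimeters. `dapi_gain` converts DNA-content
#' units to per-pixel DAPI intensity so that the integrated nuclear DAPI
#' signal is proportional to DNA content.
#'
#' @param width,height Image size in pixels.
#' @param radius_range Length-2 vector: min and max nucleus radius (pixels).
#' @param min_center_spacing Minimum perimeter gap between nuclei (pixels).
#' @param gaussian_noise_sd Additive Gaussian read noise, a.u. (0 disables).
#' @param poisson_noise If `TRUE`, pixel values are Poisson-resampled
#'   (shot noise) before read noise is added.
#' @param bit_depth Output bit depth; pixel values are integers clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param dapi_gain Scale factor from `dna_content / area` to per-pixel DAPI
#'   intensity.
#' @param seed Integer seed for placement and noise.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(width = 1024, height = 1024,
                           radius_range = c(8, 14), min_center_spacing = 2,
                           gaussian_noise_sd = 10, poisson_noise = FALSE,
                           bit_depth = 16, dapi_gain = 1000, seed = NULL) {
  stopifnot(width > 0, height > 0, length(radius_range) == 2,
            all(radius_range > 0), radius_range[1] <= radius_range[2],
            min_center_spacing >= 0, gaussian_noise_sd >= 0, dapi_gain > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 radius_range = radius_range,
                 min_center_spacing = min_center_spacing,
                 gaussian_noise_sd = gaussian_noise_sd,
                 poisson_noise = isTRUE(poisson_noise),
                 bit_depth = as.integer(bit_depth), dapi_gain = dapi_gain,
                 seed = seed),
            class = "imaging_params")
}

#' Nucleus segmentation parameters
#'
#' @param threshold_method `"otsu"` (automatic, on the smoothed channel) or
#'   `"fixed"` (use `fixed_threshold`).
#' @param fixed_threshold Intensity threshold (a.u.) when
#'   `threshold_method = "fixed"`.
#' @param min_area,max_area Area bounds (pixels); objects outside are removed.
#' @param split_touching If `TRUE`, touching nuclei are divided by a
#'   watershed on the distance transform.
#' @param smoothing_sigma Gaussian smoothing sigma (pixels) applied before
#'   thresholding; 0 disables smoothing.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area = 50, max_area = 5000,
                                split_touching = TRUE, smoothing_sigma = 2) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold) || fixed_threshold < 0))
    stop("fixed_threshold must be a nonnegative intensity when threshold_method = 'fixed'")
  stopifnot(min_area > 0, min_area < max_area, smoothing_sigma >= 0)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area = min_area, max_area = max_area,
                 split_touching = isTRUE(split_touching),
                 smoothing_sigma = smoothing_sigma),
            class = "segmentation_params")
}

#' Cell-cycle gating parameters
#'
#' @param signal_threshold_mode `"otsu_log"` places the S-gate by Otsu's
#'   method on log-transformed signal; `"k_sigma"` places it `k_sigma`
#'   standard deviations above the mean of the signal-negative component.
#' @param k_sigma Multiplier for the `"k_sigma"` mode.
#' @param g1_g2m_boundary DNA-content multiple of the G1 peak separating G1
#'   from G2/M among signal-negative events (default 1.5, i.e. 3N).
#' @return An object of class `gating_params`.
#' @export
gating_params <- function(signal_threshold_mode = c("otsu_log", "k_sigma"),
                          k_sigma = 3, g1_g2m_boundary = 1.5) {
  signal_threshold_mode <- match.arg(signal_threshold_mode)
  stopifnot(k_sigma > 0)
  if (!(g1_g2m_boundary > 1 && g1_g2m_boundary < 2))
    stop("g1_g2m_boundary must lie strictly between 1 and 2 (multiples of the G1 peak)")
  structure(list(signal_threshold_mode = signal_threshold_mode,
                 k_sigma = k_sigma, g1_g2m_boundary = g1_g2m_boundary),
            class = "gating_params")
}
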