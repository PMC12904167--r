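#' Imaging specification for synthetic fiber renders
#'
#' Describes the raster geometry and degradation model of a simulated
#' two-channel micrograph: pixel pitch, image shape, point-spread blur and
#' Poisson-Gaussian noise.  The default pitch of 0.103 um/px corresponds to
#' a 63x field in which a 200 x 400 px region covers 20.6 um x 41.2 um.
#'
#' @param pixel_pitch Physical size of one pixel, um/px.  Must be > 0.
#' @param shape Integer vector `c(rows, cols)`; rows run across the fiber
#'   width (lateral), cols along the fiber axis.  Both dims must be >= 64.
#' @param psf_sigma Gaussian point-spread sigma in um (>= 0; 0 = no blur).
#' @param noise List with `gaussian_sd` (additive read-noise SD, intensity
#'   units) and `poisson_gain` (photons per intensity unit; 0 disables shot
#'   noise).
#' @param seed Integer seed; identical seed + spec gives bit-identical
#'   output.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(pixel_pitch = 0.103,
                       shape = c(260L, 440L),
                       psf_sigma = 0.2,
                       noise = list(gaussian_sd = 0, poisson_gain = 0),
                       seed = 1L) {
  if (!is_scalar_num(pixel_pitch) || pixel_pitch <= 0)
    abort("pixel_pitch must be a positive number (um/px), got %s", format(pixel_pitch))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 64L))
    abort("shape must be c(rows, cols) with both dims >= 64")
  if (!is_scalar_num(psf_sigma) || psf_sigma < 0)
    abort("psf_sigma must be >= 0 um")
  noise <- utils::modifyList(list(gaussian_sd = 0, poisson_gain = 0), as.list(noise))
  if (noise$gaussian_sd < 0 || noise$poisson_gain < 0)
    abort("noise parameters must be >= 0")
  structure(list(pixel_pitch = pixel_pitch, shape = shape,
                 psf_sigma = psf_sigma, noise = noise,
                 seed = as.integer(seed)),
            class = "image_spec")
}

#' Geometric and photometric model of one muscle fiber
#'
#' A longitudinally sectioned fast-twitch fiber is modelled as a straight
#' horizontal band (axis along image columns) of periodic Z-line
#' striations.  Z-lines render as bright Gaussian ridges of sigma
#' `zline_sigma_um` on top of the A-band level in channel 0; channel 1
#' carries a uniform newly-synthesized-protein (NSP) background inside the
#' fiber onto which hotspots are painted.
#'
#' @param width_um Fiber width (lateral extent), um.
#' @param sarcomere_length_um Resting sarcomere length, um.  Default 2.4
#'   (mid-range for mouse plantaris at rest); configurable, never assumed
#'   by the analysis code.
#' @param zline_intensity,aband_intensity,background_intensity Channel-0
#'   levels (arbitrary units); must satisfy zline > aband >= background.
#' @param nsp_background Channel-1 level inside the fiber; hotspot blobs
#'   are rendered at `fold * nsp_background`.
#' @param nsp_outside Channel-1 level outside the fiber mask.
#' @param zline_sigma_um Axial sigma of the rendered Z-line ridge, um.
#' @return An object of class `fiber_model`.
#' @export
fiber_model <- function(width_um = 24,
                        sarcomere_length_um = 2.4,
                        zline_intensity = 200,
                        aband_intensity = 60,
                        background_intensity = 20,
                        nsp_background = 100,
                        nsp_outside = 20,
                        zline_sigma_um = 0.15) {
  if (width_um <= 0) abort("fiber width must be > 0 um")
  if (sarcomere_length_um <= 0) abort("sarcomere_length must be > 0 um")
  if (!(zline_intensity > aband_intensity && aband_intensity >= background_intensity))
    abort("intensities must satisfy zline > aband >= background")
  if (nsp_background <= 0) abort("nsp_background must be > 0")
  structure(list(width_um = width_um,
                 sarcomere_length_um = sarcomere_length_um,
                 zline_intensity = zline_intensity,
                 aband_intensity = aband_intensity,
                 background_intensity = background_intensity,
                 nsp_background = nsp_background,
                 nsp_outside = nsp_outside,
                 zline_sigma_um = zline_sigma_um),
            class = "fiber_model")
}

#' A planted sarcomere transverse-split event
#'
#' A transverse split is a Y-shaped bifurcation of a Z-line across the
#' fiber width: on the far lateral side of the fork the fiber carries one
#' extra (sense +1) or one fewer (sense -1) in-series sarcomere.  The
#' bifurcating Z-line is the one shared by A-band gaps `aband_index` and
#' `aband_index + 1` (gap j lies between Z-lines j and j+1, 1-based).
#'
#' @param aband_index Which inter-Z-line gap carries the event; the fork
#'   sits at that gap's far (right) bounding Z-line.
#' @param lateral_fraction Position of the fork across the fiber width,
#'   strictly inside (0, 1), measured from the near (low-row) fiber edge.
#' @param sense +1 for a bifurcation (one extra sarcomere beyond the
#'   fork), -1 for a merge.
#' @return An object of class `split_event`.
#' @export
split_event <- function(aband_index, lateral_fraction, sense = 1L) {
  if (!is_scalar_num(lateral_fraction) || lateral_fraction <= 0 || lateral_fraction >= 1)
    abort("lateral_fraction must lie strictly inside (0, 1)")
  if (!sense %in% c(1L, -1L)) abort("sense must be +1 or -1")
  structure(list(aband_index = as.integer(aband_index),
                 lateral_fraction = lateral_fraction,
                 sense = as.integer(sense)),
            class = "split_event")
}

#' Classes of NSP hotspot morphology
#' @export
HOTSPOT_CLASSES <- c("yu", "rodier", "hzone", "short_atypical", "long_atypical")

#' A planted newly-synthesized-protein hotspot
#'
#' The hotspot's axial footprint follows its sarcomerogenesis model class:
#' `yu` spans exactly one sarcomere Z-to-Z; `rodier` exactly two
#' in-series sarcomeres Z-to-Z; `hzone` spans one sarcomere length but is
#' centered on a Z-line (it occupies the adjacent inner halves of two
#' in-series sarcomeres); `short_atypical` spans < 2 sarcomeres without
#' Z-registration and `long_atypical` > 2 sarcomeres.
#'
#' @param model_class One of [HOTSPOT_CLASSES].
#' @param anchor_sarcomere 1-based index of the sarcomere (gap) at which
#'   the hotspot starts.
#' @param lateral_fraction Lateral position of the blob centre in (0, 1).
#' @param diameter Transverse blob diameter, nm.
#' @param fold Enrichment of mean blob intensity over the local NSP
#'   background (> 0).
#' @param span_sarcomeres Axial span in sarcomere units; only honoured for
#'   the atypical classes (must be < 2 for short, > 2 for long).
#' @return An object of class `hotspot_spec`.
#' @export
hotspot_spec <- function(model_class, anchor_sarcomere, lateral_fraction = 0.5,
                         diameter = 1000, fold = 3, span_sarcomeres = NULL) {
  model_class <- match.arg(model_class, HOTSPOT_CLASSES)
  if (diameter <= 0) abort("hotspot diameter must be > 0 nm")
  if (fold <= 0) abort("hotspot fold must be > 0")
  if (lateral_fraction <= 0 || lateral_fraction >= 1)
    abort("lateral_fraction must lie strictly inside (0, 1)")
  if (model_class == "short_atypical") {
    if (is.null(span_sarcomeres)) span_sarcomeres <- 0.6
    if (span_sarcomeres >= 2) abort("short_atypical span must be < 2 sarcomeres")
  } else if (model_class == "long_atypical") {
    if (is.null(span_sarcomeres)) span_sarcomeres <- 3
    if (span_sarcomeres <= 2) abort("long_atypical span must be > 2 sarcomeres")
  } else if (!is.null(span_sarcomeres)) {
    abort("span_sarcomeres is only configurable for the atypical classes")
  }
  structure(list(model_class = model_class,
                 anchor_sarcomere = as.integer(anchor_sarcomere),
                 lateral_fraction = lateral_fraction,
                 diameter = diameter, fold = fold,
                 span_sarcomeres = span_sarcomeres),
            class = "hotspot_spec")
}
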