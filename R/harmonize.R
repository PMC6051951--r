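#' Harmonization target
#'
#' The common comparison space two scanners' images are brought to: a shared
#' reconstructed resolution (7.0 mm FWHM by default, matching the coarsest
#' clinical reconstruction) and a shared voxel grid spacing (2.1 x 2.1 x 2.4
#' mm³ by default).
#'
#' @param target_fwhm Common resolution FWHM, mm. Must be >= every input
#'   scanner's native resolution, since matched filtering can only add blur.
#' @param target_spacing Common voxel spacing, mm (length 3 or scalar).
#'
#' @return An object of class `harmonization_target`.
#' @export
harmonization_target <- function(target_fwhm = 7.0,
                                 target_spacing = c(2.1, 2.1, 2.4)) {
  if (!is.finite(target_fwhm) || target_fwhm < 0) {
    stop("target_fwhm must be >= 0", call. = FALSE)
  }
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0)) {
    stop("target_spacing must be 3 positive numbers (mm)", call. = FALSE)
  }
  structure(list(target_fwhm = as.numeric(target_fwhm),
                 target_spacing = target_spacing),
            class = "harmonization_target")
}

#' Matched-filter FWHM by Gaussian quadrature
#'
#' The additional Gaussian filter that takes an image from its native
#' resolution to the target resolution, under the standard assumption that
#' point-spread functions compose in quadrature:
#' `fwhm_filter = sqrt(target^2 - current^2)`.
#'
#' @param current_fwhm Native resolution FWHM, mm (>= 0).
#' @param target_fwhm Target resolution FWHM, mm (>= current_fwhm).
#' @return The matched filter FWHM, mm.
#' @examples
#' matched_filter_fwhm(6.3, 7.0)  # ~3.05 mm
#' @export
matched_filter_fwhm <- function(current_fwhm, target_fwhm) {
  if (!is.finite(current_fwhm) || current_fwhm < 0) {
    stop("current_fwhm must be >= 0", call. = FALSE)
  }
  if (!is.finite(target_fwhm) || target_fwhm < current_fwhm) {
    stop("cannot sharpen by smoothing: target_fwhm (", target_fwhm,
         ") < current_fwhm (", current_fwhm, ")", call. = FALSE)
  }
  sqrt(target_fwhm^2 - current_fwhm^2)
}

#' Isotropic Gaussian smoothing of a volume
#'
#' Convolves the volume with an isotropic Gaussian of the given FWHM in
#' physical mm (per-axis sigma `fwhm / (2 sqrt(2 ln 2)) / spacing` voxels).
#' The field is treated as zero outside the grid (zero-padding), so values
#' within a few sigma of the border are attenuated; lesions are assumed
#' interior. `fwhm = 0` returns the input unchanged.
#'
#' @param volume An [activity_volume()].
#' @param fwhm Filter FWHM, mm (>= 0).
#' @return The smoothed [activity_volume()] on the same grid.
#' @export
gaussian_smooth <- function(volume, fwhm) {
  if (!is.finite(fwhm) || fwhm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (fwhm == 0) return(volume)
  g <- vol_grid(volume)
  sigma_vox <- fwhm * FWHM_TO_SIGMA / g$spacing
  new_volume_like(gaussian_blur_array(unclass(volume), sigma_vox), volume,
                  note = list(step = "smooth", fwhm = fwhm))
}

#' Trilinear resampling onto a target grid
#'
#' Evaluates the source field at every target voxel center (world
#' coordinates) by trilinear interpolation. Target centers at or beyond the
#' source edge are clamped to the edge value; the target extent should lie
#' within the source extent.
#'
#' @param volume Source [activity_volume()].
#' @param target Target [pet_grid()].
#' @return An [activity_volume()] on `target`.
#' @export
resample_to_grid <- function(volume, target) {
  stopifnot(inherits(target, "pet_grid"))
  g <- vol_grid(volume)
  if (grids_equal(g, target)) return(volume)
  idx <- scanner_grid_index_matrix(target, g)
  vals <- trilinear_at_index(unclass(volume), idx)
  new_volume_like(array(vals, dim = target$shape), volume, grid = target,
                  note = list(step = "resample", spacing = target$spacing))
}

#' Prompt-gamma-coincidence correction
#'
#' The imaged ¹²⁴I AC is `pgc_factor * true` (e.g. underestimated by 20% for
#' a factor of 0.8), so correction *divides* the imaged values by the factor
#' to restore the true scale.
#'
#' @param x An [activity_volume()] or a numeric vector of AC values.
#' @param pgc_factor Recovery factor in (0, 1].
#' @return Same kind as `x`, rescaled by `1 / pgc_factor`.
#' @examples
#' pgc_correct(8, 0.8)  # 10
#' @export
pgc_correct <- function(x, pgc_factor) {
  if (!is.finite(pgc_factor) || pgc_factor <= 0 || pgc_factor > 1) {
    stop("pgc_factor must be in (0, 1]", call. = FALSE)
  }
  if (inherits(x, "activity_volume")) {
    new_volume_like(unclass(x) / pgc_factor, x,
                    note = list(step = "pgc_correct", factor = pgc_factor))
  } else {
    x / pgc_factor
  }
}

#' Harmonize a volume to the common comparison space
#'
#' Applies, in order: (1) the matched Gaussian filter bringing the native
#' resolution to the target FWHM ([matched_filter_fwhm()], applied on the
#' native grid where the most information is available); (2) trilinear
#' resampling to the common grid; (3) PGC rescaling. The three applied
#' parameters are recorded in the volume's provenance.
#'
#' @param volume Native [activity_volume()] from `scanner`.
#' @param scanner The [scanner_model()] that produced `volume`.
#' @param target A [harmonization_target()].
#' @param target_grid Optional explicit common [pet_grid()]; by default a grid
#'   at `target$target_spacing` covering the volume's extent from its origin.
#' @param apply_pgc,apply_resolution Logical switches for the two correction
#'   families (PGC scaling; resolution + grid matching). Both `TRUE` gives
#'   full harmonization; switching either off reproduces the partially
#'   corrected comparison modes.
#'
#' @return The harmonized [activity_volume()].
#' @export
harmonize_volume <- function(volume, scanner, target = harmonization_target(),
                             target_grid = NULL, apply_pgc = TRUE,
                             apply_resolution = TRUE) {
  stopifnot(inherits(scanner, "scanner_model"),
            inherits(target, "harmonization_target"))
  out <- volume
  if (apply_resolution) {
    f <- matched_filter_fwhm(scanner$resolution_fwhm, target$target_fwhm)
    out <- gaussian_smooth(out, f)
    if (is.null(target_grid)) {
      g <- vol_grid(volume)
      ext <- grid_extent(g)
      span <- ext["hi", ] - ext["lo", ]
      shape <- pmax(floor(span / target$target_spacing + 1e-9) + 1L, 1L)
      target_grid <- pet_grid(shape, target$target_spacing, origin = ext["lo", ])
    }
    out <- resample_to_grid(out, target_grid)
  }
  if (apply_pgc) out <- pgc_correct(out, scanner$pgc_factor)
  out
}
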