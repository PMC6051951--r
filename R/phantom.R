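#' Virtual PET scanner model
#'
#' Describes a scanner's imaging characteristics as seen by the forward model:
#' the reconstructed voxel grid spacing, the reconstructed spatial resolution
#' (isotropic Gaussian FWHM), the prompt-gamma-coincidence (PGC) recovery
#' factor, and a noise coefficient.
#'
#' ¹²⁴I is a non-pure positron emitter: about 12% of decays emit a 605-keV
#' prompt gamma in cascade with the positron, producing spurious coincidences
#' that bias the imaged activity concentration downward. `pgc_factor` is the
#' fraction of the true AC that the scanner images (e.g. 0.8 means a 20%
#' underestimation).
#'
#' @param name Scanner label.
#' @param grid_spacing Reconstructed voxel spacing, mm (length 3 or scalar).
#' @param resolution_fwhm Reconstructed spatial resolution FWHM, mm (>= 0,
#'   isotropic).
#' @param pgc_factor PGC recovery factor in (0, 1].
#' @param noise_coeff Noise coefficient c >= 0; simulated noise is zero-mean
#'   Gaussian with per-voxel SD `c * sqrt(max(AC, 0))`, so relative noise
#'   falls as 1/sqrt(AC), the Poisson-like behaviour of reconstructed PET.
#' @param emission_time Emission time per bed position, minutes (metadata
#'   only; differing emission times are why two scanners get different
#'   `noise_coeff`).
#'
#' @return An object of class `scanner_model`.
#' @examples
#' scanner_model("duo", c(1.73, 1.73, 2.43), 6.7, pgc_factor = 0.8)
#' @export
scanner_model <- function(name, grid_spacing, resolution_fwhm, pgc_factor = 1,
                          noise_coeff = 0, emission_time = NA_real_) {
  if (length(grid_spacing) == 1L) grid_spacing <- rep(grid_spacing, 3L)
  grid_spacing <- as.numeric(grid_spacing)
  stopifnot(length(grid_spacing) == 3L)
  if (any(grid_spacing <= 0)) stop("grid_spacing must be positive", call. = FALSE)
  if (!is.finite(resolution_fwhm) || resolution_fwhm < 0) {
    stop("resolution_fwhm must be >= 0", call. = FALSE)
  }
  if (!is.finite(pgc_factor) || pgc_factor <= 0 || pgc_factor > 1) {
    stop("pgc_factor must be in (0, 1]", call. = FALSE)
  }
  if (!is.finite(noise_coeff) || noise_coeff < 0) {
    stop("noise_coeff must be >= 0", call. = FALSE)
  }
  structure(
    list(name = as.character(name), grid_spacing = grid_spacing,
         resolution_fwhm = as.numeric(resolution_fwhm),
         pgc_factor = as.numeric(pgc_factor),
         noise_coeff = as.numeric(noise_coeff),
         emission_time = as.numeric(emission_time)),
    class = "scanner_model"
  )
}

#' @export
print.scanner_model <- function(x, ...) {
  cat(sprintf(
    "<scanner_model> %s: spacing %.3g x %.3g x %.3g mm, FWHM %.2f mm, pgc %.2f, noise %.2f\n",
    x$name, x$grid_spacing[1], x$grid_spacing[2], x$grid_spacing[3],
    x$resolution_fwhm, x$pgc_factor, x$noise_coeff))
  invisible(x)
}

#' Lesion specification table
#'
#' Builds (and validates) a tibble of spherical lesion specifications: one row
#' per lesion with its world-coordinate center (mm), diameter (mm), true
#' activity concentration (kBq/mL), and distance from the trachea surface
#' (mm). This is the lesion manifest format used throughout the package.
#'
#' @param id Lesion labels (unique).
#' @param center_x_mm,center_y_mm,center_z_mm Lesion center coordinates, mm.
#' @param diameter_mm Sphere diameters, mm (> 0).
#' @param ac_kbq_ml True activity concentrations, kBq/mL (>= 0).
#' @param trachea_distance_mm Distance from the trachea surface, mm (>= 0);
#'   lesions with distance <= 5 mm are classed "adjacent", others "distant".
#'
#' @return A tibble with class `lesion_manifest`.
#' @export
lesion_manifest <- function(id, center_x_mm, center_y_mm, center_z_mm,
                            diameter_mm, ac_kbq_ml, trachea_distance_mm) {
  tb <- tibble::tibble(
    id = as.character(id),
    center_x_mm = as.numeric(center_x_mm),
    center_y_mm = as.numeric(center_y_mm),
    center_z_mm = as.numeric(center_z_mm),
    diameter_mm = as.numeric(diameter_mm),
    ac_kbq_ml = as.numeric(ac_kbq_ml),
    trachea_distance_mm = as.numeric(trachea_distance_mm)
  )
  validate_lesions(tb)
  class(tb) <- c("lesion_manifest", class(tb))
  tb
}

validate_lesions <- function(tb) {
  need <- c("id", "center_x_mm", "center_y_mm", "center_z_mm",
            "diameter_mm", "ac_kbq_ml", "trachea_distance_mm")
  missing <- setdiff(need, names(tb))
  if (length(missing)) {
    stop("lesion manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tb$id)) stop("lesion ids must be unique", call. = FALSE)
  if (any(tb$diameter_mm <= 0)) stop("lesion diameters must be > 0", call. = FALSE)
  if (any(tb$ac_kbq_ml < 0)) stop("lesion ACs must be >= 0", call. = FALSE)
  if (any(tb$trachea_distance_mm < 0)) {
    stop("trachea distances must be >= 0", call. = FALSE)
  }
  invisible(tb)
}

lesion_centers <- function(lesions) {
  as.matrix(lesions[, c("center_x_mm", "center_y_mm", "center_z_mm")])
}

#' Sample a random neck-lesion population
#'
#' Draws a non-overlapping set of spherical lesions inside a grid's interior,
#' emulating the spread seen in clinical ¹²⁴I neck imaging of differentiated
#' thyroid cancer: activity concentrations log-uniform over roughly three
#' decades (default 0.2 to 800 kBq/mL), diameters 5-20 mm, and trachea-surface
#' distances uniform on 0-30 mm so about one lesion in six falls in the
#' "adjacent" (<= 5 mm) class.
#'
#' Centers are drawn by rejection sampling with a minimum surface-to-surface
#' gap, so the ground-truth spheres never overlap.
#'
#' @param n Number of lesions.
#' @param grid The [pet_grid()] the ground truth will be built on.
#' @param seed Integer seed (the draw is deterministic given the seed).
#' @param diameter_range,ac_range,trachea_range Length-2 numeric ranges for
#'   diameters (mm), ACs (kBq/mL, log-uniform), and trachea distances (mm).
#' @param margin_mm Clearance kept between a lesion surface and the grid edge
#'   (and between lesion surfaces), mm.
#'
#' @return A [lesion_manifest()] tibble with `n` rows.
#' @export
sample_lesions <- function(n, grid, seed, diameter_range = c(5, 20),
                           ac_range = c(0.2, 800), trachea_range = c(0, 30),
                           margin_mm = 4) {
  stopifnot(inherits(grid, "pet_grid"), n >= 1)
  ext <- grid_extent(grid)
  withr::with_seed(seed, {
    diam <- stats::runif(n, diameter_range[1], diameter_range[2])
    ac <- exp(stats::runif(n, log(ac_range[1]), log(ac_range[2])))
    tdist <- stats::runif(n, trachea_range[1], trachea_range[2])
    centers <- matrix(NA_real_, n, 3)
    placed <- 0L
    tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 20000L) {
        stop("could not place ", n, " non-overlapping lesions in the grid; ",
             "enlarge the grid or reduce n", call. = FALSE)
      }
      r <- diam[placed + 1L] / 2 + margin_mm
      cand <- vapply(1:3, function(a) stats::runif(1, ext["lo", a] + r, ext["hi", a] - r),
                     numeric(1))
      if (ext["hi", 1] - ext["lo", 1] < 2 * r) {
        stop("grid too small for lesion of diameter ", diam[placed + 1L], call. = FALSE)
      }
      ok <- TRUE
      if (placed > 0L) {
        dd <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))
        ok <- all(dd > (diam[seq_len(placed)] + diam[placed + 1L]) / 2 + margin_mm)
      }
      if (ok) {
        placed <- placed + 1L
        centers[placed, ] <- cand
      }
    }
    lesion_manifest(
      id = sprintf("L%02d", seq_len(n)),
      center_x_mm = centers[, 1], center_y_mm = centers[, 2],
      center_z_mm = centers[, 3],
      diameter_mm = diam, ac_kbq_ml = ac, trachea_distance_mm = tdist
    )
  })
}

#' Build a ground-truth activity map
#'
#' Paints spherical lesions onto a uniform background: every voxel whose
#' *center* lies within a lesion sphere (Euclidean distance in mm from the
#' lesion center <= diameter/2) carries that lesion's activity concentration;
#' all other voxels carry `background_ac`. No partial-volume weighting is
#' applied in the truth — finite resolution is the scanner model's job
#' ([simulate_scan()]).
#'
#' @param lesions A [lesion_manifest()] (may have zero rows).
#' @param background_ac Background activity concentration, kBq/mL (>= 0).
#' @param grid The [pet_grid()] to paint on.
#'
#' @return A ground-truth [activity_volume()].
#' @export
build_ground_truth <- function(lesions, background_ac, grid) {
  stopifnot(inherits(grid, "pet_grid"))
  if (!is.finite(background_ac) || background_ac < 0) {
    stop("background_ac must be >= 0", call. = FALSE)
  }
  lesions <- validate_lesions(tibble::as_tibble(lesions))
  n <- nrow(lesions)
  ext <- grid_extent(grid)
  if (n > 0) {
    centers <- lesion_centers(lesions)
    r <- lesions$diameter_mm / 2
    for (i in seq_len(n)) {
      if (any(centers[i, ] - r[i] < ext["lo", ] - 1e-9) ||
          any(centers[i, ] + r[i] > ext["hi", ] + 1e-9)) {
        stop("lesion '", lesions$id[i], "' extends outside the grid", call. = FALSE)
      }
    }
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        if (sqrt(sum((centers[i, ] - centers[j, ])^2)) < r[i] + r[j]) {
          stop("lesions '", lesions$id[i], "' and '", lesions$id[j],
               "' overlap", call. = FALSE)
        }
      }
    }
  }
  values <- array(background_ac, dim = grid$shape)
  ax <- grid_axes(grid)
  for (i in seq_len(n)) {
    ctr <- c(lesions$center_x_mm[i], lesions$center_y_mm[i], lesions$center_z_mm[i])
    rad <- lesions$diameter_mm[i] / 2
    # bounding box of candidate voxels, then exact center-in-sphere test
    sel <- lapply(1:3, function(a) which(abs(ax[[a]] - ctr[a]) <= rad))
    if (any(lengths(sel) == 0L)) next
    d2 <- outer(outer((ax[[1]][sel[[1]]] - ctr[1])^2,
                      (ax[[2]][sel[[2]]] - ctr[2])^2, "+"),
                (ax[[3]][sel[[3]]] - ctr[3])^2, "+")
    inside <- d2 <= rad^2 + 1e-12
    sub <- values[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
    sub[inside] <- lesions$ac_kbq_ml[i]
    values[sel[[1]], sel[[2]], sel[[3]]] <- sub
  }
  out <- activity_volume(values, grid, ground_truth = TRUE)
  attr(out, "provenance") <- list(ground_truth = list(step = "ground_truth",
                                                      n_lesions = n,
                                                      background_ac = background_ac))
  out
}

#' Simulate a scanner's observation of a ground-truth map
#'
#' Forward model of the two effects the harmonization pipeline later corrects,
#' plus noise:
#' 1. finite reconstructed resolution — isotropic Gaussian blur of FWHM
#'    `scanner$resolution_fwhm`, applied on the (finer) truth grid;
#' 2. reconstruction onto the scanner's voxel grid — trilinear resampling;
#' 3. PGC underestimation — multiplication by `scanner$pgc_factor`;
#' 4. zero-mean Gaussian noise with per-voxel SD
#'    `noise_coeff * sqrt(max(AC, 0))`.
#'
#' The result is deterministic for a fixed `seed`.
#'
#' @param truth A ground-truth [activity_volume()], on a grid at least as fine
#'   as the scanner grid on every axis.
#' @param scanner A [scanner_model()].
#' @param seed Integer seed for the noise draw.
#' @param scanner_grid Optional [pet_grid()] overriding the default scanner
#'   grid (which covers the truth extent at `scanner$grid_spacing`, sharing
#'   the truth origin).
#'
#' @return An observed [activity_volume()] on the scanner grid.
#' @export
simulate_scan <- function(truth, scanner, seed, scanner_grid = NULL) {
  stopifnot(inherits(scanner, "scanner_model"))
  tg <- vol_grid(truth)
  if (any(tg$spacing > scanner$grid_spacing + 1e-9)) {
    stop("truth grid must be at least as fine as the scanner grid on every axis",
         call. = FALSE)
  }
  if (is.null(scanner_grid)) {
    ext <- grid_extent(tg)
    span <- ext["hi", ] - ext["lo", ]
    shape <- pmax(floor(span / scanner$grid_spacing + 1e-9) + 1L, 1L)
    scanner_grid <- pet_grid(shape, scanner$grid_spacing, origin = ext["lo", ])
  }
  sigma_vox <- scanner$resolution_fwhm * FWHM_TO_SIGMA / tg$spacing
  blurred <- gaussian_blur_array(unclass(truth), sigma_vox)
  idx <- scanner_grid_index_matrix(scanner_grid, tg)
  vals <- trilinear_at_index(blurred, idx)
  vals <- vals * scanner$pgc_factor
  if (scanner$noise_coeff > 0) {
    sdv <- scanner$noise_coeff * sqrt(pmax(vals, 0))
    vals <- withr::with_seed(seed, vals + stats::rnorm(length(vals), 0, sdv))
  }
  out <- suppressWarnings(activity_volume(array(vals, dim = scanner_grid$shape),
                                          scanner_grid))
  # negatives from noise are flagged in provenance, never clipped
  attr(out, "provenance") <- c(attr(truth, "provenance"),
                               list(scan = list(step = "scan", scanner = scanner$name,
                                                fwhm = scanner$resolution_fwhm,
                                                pgc = scanner$pgc_factor,
                                                noise = scanner$noise_coeff,
                                                seed = seed,
                                                n_negative = sum(vals < 0))))
  out
}

# continuous source-grid indices of every target voxel center (n x 3)
scanner_grid_index_matrix <- function(target_grid, source_grid) {
  ax <- grid_axes(target_grid)
  centers <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                   KEEP.OUT.ATTRS = FALSE))
  # expand.grid varies the first factor fastest, matching R array order
  world_to_index(source_grid, centers)
}
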