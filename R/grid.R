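#' Regular 3D voxel grid
#'
#' A `pet_grid` describes a regular 3D sampling lattice in world (scanner)
#' coordinates: the number of voxels per axis, the voxel spacing in mm, and
#' the world coordinate of the *center* of voxel index `(0, 0, 0)`. The world
#' coordinate of voxel `(i, j, k)` (0-based) is `origin + c(i, j, k) * spacing`,
#' exactly.
#'
#' @param shape Integer vector of length 3: voxels per axis (each >= 1).
#' @param spacing Numeric vector of length 3: voxel spacing in mm (each > 0).
#'   A single value is recycled to an isotropic spacing.
#' @param origin Numeric vector of length 3: world coordinate (mm) of the
#'   center of voxel `(0, 0, 0)`. Default `c(0, 0, 0)`.
#'
#' @return An object of class `pet_grid`.
#' @examples
#' g <- pet_grid(c(60, 60, 50), spacing = 1)
#' grid_extent(g)
#' @export
pet_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L)) {
    stop("`shape` must be 3 integers, each >= 1", call. = FALSE)
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || anyNA(origin)) {
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  }
  structure(
    list(shape = shape, spacing = spacing, origin = origin),
    class = "pet_grid"
  )
}

#' @export
print.pet_grid <- function(x, ...) {
  cat(sprintf(
    "<pet_grid> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

#' @export
format.pet_grid <- function(x, ...) {
  sprintf("%dx%dx%d @ %.3gx%.3gx%.3g mm", x$shape[1], x$shape[2], x$shape[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

grids_equal <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World extent of a grid
#'
#' Returns the world-coordinate range spanned by voxel *centers* along each
#' axis (a 2 x 3 matrix: rows `lo`, `hi`).
#'
#' @param grid A [pet_grid()].
#' @return A 2 x 3 numeric matrix in mm.
#' @export
grid_extent <- function(grid) {
  stopifnot(inherits(grid, "pet_grid"))
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1L) * grid$spacing
  m <- rbind(lo = pmin(lo, hi), hi = pmax(lo, hi))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Voxel-center world coordinates along each axis
#'
#' @param grid A [pet_grid()].
#' @return A list of three numeric vectors (x, y, z voxel-center coordinates, mm).
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "pet_grid"))
  lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
}

#' Activity-concentration volume
#'
#' An `activity_volume` couples a 3D array of activity concentrations
#' (kBq/mL) with the [pet_grid()] it is sampled on. Ground-truth volumes must
#' be non-negative; observed (simulated or measured) volumes may carry small
#' negative excursions from noise — these are flagged with a warning, never
#' clipped, so downstream statistics see the data as reconstructed.
#'
#' @param values 3D numeric array, shape equal to `grid$shape`.
#' @param grid A [pet_grid()].
#' @param ground_truth Logical; if `TRUE`, negative values are an error rather
#'   than a warning.
#'
#' @return An object of class `activity_volume` (the array, with the grid and
#'   provenance attached as attributes).
#' @export
activity_volume <- function(values, grid, ground_truth = FALSE) {
  stopifnot(inherits(grid, "pet_grid"))
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$shape)) {
    stop("`values` must be a 3D array with dim equal to grid$shape", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("`values` must be finite", call. = FALSE)
  if (any(values < 0)) {
    if (ground_truth) {
      stop("ground-truth activity must be non-negative", call. = FALSE)
    }
    warning(sprintf("volume contains %d negative voxels (noise); kept unclipped",
                    sum(values < 0)), call. = FALSE)
  }
  structure(values, grid = grid, provenance = list(),
            class = c("activity_volume", "array"))
}

#' @export
print.activity_volume <- function(x, ...) {
  g <- vol_grid(x)
  v <- as.vector(x)
  cat(sprintf("<activity_volume> %s; AC range [%.4g, %.4g] kBq/mL\n",
              format(g), min(v), max(v)))
  prov <- attr(x, "provenance")
  if (length(prov)) {
    cat("provenance:", paste(names(prov), vapply(prov, function(p)
      paste(format(unlist(p)), collapse = ","), ""), sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Grid of a volume
#' @param volume An [activity_volume()].
#' @return The [pet_grid()] the volume is sampled on.
#' @export
vol_grid <- function(volume) {
  g <- attr(volume, "grid")
  if (is.null(g)) stop("not an activity_volume: no grid attribute", call. = FALSE)
  g
}

# rebuild a volume from raw values, carrying over grid + provenance
new_volume_like <- function(values, template, grid = NULL, note = NULL) {
  g <- if (is.null(grid)) vol_grid(template) else grid
  out <- structure(as.array(values), grid = g,
                   provenance = attr(template, "provenance"),
                   class = c("activity_volume", "array"))
  if (!is.null(note)) {
    prov <- attr(out, "provenance")
    prov[[length(prov) + 1L]] <- note
    names(prov)[length(prov)] <- note$step
    attr(out, "provenance") <- prov
  }
  out
}

# world coordinates (n x 3, mm) -> continuous 0-based voxel index (n x 3)
world_to_index <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

# 0-based index (n x 3) -> world coordinates (n x 3, mm)
index_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk, 2, grid$spacing, "*"), 2, grid$origin, "+")
}
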