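#' Write an activity volume as NIfTI-1
#'
#' Encodes the grid in the NIfTI sform/qform affine (diagonal, RAS-like:
#' world = origin + index * spacing, 0-based indices, mm) and stores voxel
#' values as float64, so a round trip through [read_volume_nifti()]
#' reproduces grid and values exactly.
#'
#' @param volume An [activity_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  g <- vol_grid(volume)
  img <- RNifti::asNifti(array(as.numeric(volume), dim = g$shape))
  RNifti::pixdim(img) <- g$spacing   # must precede the xform: scales live here
  affine <- diag(4)
  diag(affine)[1:3] <- g$spacing
  affine[1:3, 4] <- g$origin
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read an activity volume from NIfTI-1
#'
#' Inverse of [write_volume_nifti()]. The affine must be diagonal with
#' positive scales (the axis-aligned grids this package produces).
#'
#' @param path NIfTI file path.
#' @return An [activity_volume()].
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- unclass(RNifti::xform(img))
  rot <- affine[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6 * max(abs(diag(rot))) ||
      any(diag(rot) <= 0)) {
    stop("only axis-aligned NIfTI volumes with positive scales are supported",
         call. = FALSE)
  }
  g <- pet_grid(dim(img), spacing = diag(rot), origin = affine[1:3, 4])
  suppressWarnings(activity_volume(array(as.numeric(img), dim = g$shape), g))
}

#' Write a phantom bundle to disk
#'
#' Serializes one simulated study: the ground-truth volume, every observed
#' volume (NIfTI, grid in the header affine), the lesion manifest CSV (header
#' `id,center_x_mm,center_y_mm,center_z_mm,diameter_mm,ac_kbq_ml,trachea_distance_mm`),
#' and a JSON manifest recording the scanner models and seeds.
#'
#' @param truth Ground-truth [activity_volume()].
#' @param observed Named list of observed [activity_volume()]s.
#' @param lesions A [lesion_manifest()].
#' @param directory Output directory (created if missing).
#' @param scanners Optional named list of [scanner_model()]s (names matching
#'   `observed`).
#' @param seeds Optional named list/vector of the seeds used per volume.
#' @return Path of the JSON manifest.
#' @export
write_phantom_bundle <- function(truth, observed, lesions, directory,
                                 scanners = NULL, seeds = NULL) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(directory)) {
      stop("cannot create directory ", directory, call. = FALSE)
    }
  }
  if (is.null(names(observed)) || any(names(observed) == "")) {
    stop("`observed` must be a named list of volumes", call. = FALSE)
  }
  lesions <- validate_lesions(tibble::as_tibble(lesions))
  write_volume_nifti(truth, file.path(directory, "truth.nii.gz"))
  vol_files <- stats::setNames(
    vapply(names(observed), function(nm) paste0(nm, ".nii.gz"), ""),
    names(observed)
  )
  for (nm in names(observed)) {
    write_volume_nifti(observed[[nm]], file.path(directory, vol_files[[nm]]))
  }
  readr::write_csv(lesions, file.path(directory, "lesions.csv"))
  manifest <- list(
    format = "petharm phantom bundle v1",
    axis_order = "RAS-like: world = origin + index * spacing, 0-based voxel indices, mm",
    truth = "truth.nii.gz",
    volumes = as.list(vol_files),
    lesions = "lesions.csv",
    scanners = if (is.null(scanners)) NULL else
      lapply(scanners, function(s) unclass(s)),
    seeds = as.list(seeds)
  )
  manifest_path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  manifest_path
}

#' Read a phantom bundle written by [write_phantom_bundle()]
#'
#' @param directory Bundle directory.
#' @return A list with `truth`, `observed` (named list of volumes), `lesions`
#'   (tibble), and `manifest` (the parsed JSON).
#' @export
read_phantom_bundle <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"))
  observed <- lapply(manifest$volumes, function(f)
    read_volume_nifti(file.path(directory, f)))
  lesions <- readr::read_csv(file.path(directory, manifest$lesions),
                             show_col_types = FALSE)
  list(truth = read_volume_nifti(file.path(directory, manifest$truth)),
       observed = observed,
       lesions = validate_lesions(lesions),
       manifest = manifest)
}
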