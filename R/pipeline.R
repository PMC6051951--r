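#' Configuration of a dual-scanner comparison study
#'
#' Everything one end-to-end run needs: the ground-truth grid and lesion
#' population, the two virtual scanners, the harmonization target, the
#' quantification settings, and (optionally) a TIAC uncertainty sweep.
#'
#' The defaults define the package's reference study conditions: a 1-mm
#' isotropic truth grid over a neck-sized field of view; a reference
#' PET/CT-like scanner (1.73 x 1.73 x 2.43 mm³ voxels, 6.7 mm FWHM, 20% PGC
#' underestimation) against a test PET/MR-like scanner (2.09 x 2.09 x 2.03
#' mm³, 6.3 mm FWHM, 10% PGC underestimation); 40 lesions spanning 0.2-800
#' kBq/mL; and noise coefficients reflecting the reference system's longer
#' emission time.
#'
#' @param grid Truth [pet_grid()].
#' @param background_ac Background AC, kBq/mL.
#' @param lesions A [lesion_manifest()], or `NULL` to sample `n_lesions`
#'   with [sample_lesions()] under `lesion_seed`.
#' @param n_lesions,lesion_seed Lesion sampling controls (used when
#'   `lesions` is `NULL`).
#' @param ref_scanner,test_scanner [scanner_model()]s.
#' @param scan_seeds Integer seeds, named `ref` and `test`, one per simulated
#'   volume.
#' @param target A [harmonization_target()].
#' @param search_radius,voi_diameter,exclusion_threshold See [measure_pair()].
#' @param mean_limit,sd_limit Acceptance bounds, percentage points.
#' @param tiac Optional list with `rel_sd_levels`, `t_eff_list`, `n_draws`,
#'   `seed` to run [sweep_tiac_uncertainty()] as part of the study; `NULL`
#'   to skip.
#' @return A list of class `study_config`.
#' @export
study_config <- function(grid = pet_grid(c(150, 150, 120), 1.0),
                         background_ac = 0.05,
                         lesions = NULL, n_lesions = 40, lesion_seed = 101,
                         ref_scanner = scanner_model("ref_petct",
                                                     c(1.73, 1.73, 2.43), 6.7,
                                                     pgc_factor = 0.8,
                                                     noise_coeff = 0.4,
                                                     emission_time = 3.5),
                         test_scanner = scanner_model("test_petmr",
                                                      c(2.09, 2.09, 2.03), 6.3,
                                                      pgc_factor = 0.9,
                                                      noise_coeff = 0.6,
                                                      emission_time = 3),
                         scan_seeds = c(ref = 211, test = 212),
                         target = harmonization_target(),
                         search_radius = 10, voi_diameter = 7.0,
                         exclusion_threshold = 1.0,
                         mean_limit = 10, sd_limit = 25,
                         tiac = list(rel_sd_levels = c(0.05, 0.10, 0.15, 0.20, 0.25),
                                     t_eff_list = c(24, 48, 72, 96),
                                     n_draws = 1e5, seed = 7)) {
  stopifnot(inherits(grid, "pet_grid"),
            inherits(ref_scanner, "scanner_model"),
            inherits(test_scanner, "scanner_model"),
            inherits(target, "harmonization_target"))
  if (!all(c("ref", "test") %in% names(scan_seeds))) {
    stop("scan_seeds must carry a seed for every stochastic stage ('ref', 'test')",
         call. = FALSE)
  }
  if (!is.null(lesions)) validate_lesions(tibble::as_tibble(lesions))
  structure(
    list(grid = grid, background_ac = background_ac, lesions = lesions,
         n_lesions = n_lesions, lesion_seed = lesion_seed,
         ref_scanner = ref_scanner, test_scanner = test_scanner,
         scan_seeds = scan_seeds, target = target,
         search_radius = search_radius, voi_diameter = voi_diameter,
         exclusion_threshold = exclusion_threshold,
         mean_limit = mean_limit, sd_limit = sd_limit, tiac = tiac),
    class = "study_config"
  )
}

#' Read a study configuration from YAML
#'
#' A text twin of [study_config()]: top-level keys `grid` (`shape`,
#' `spacing_mm`, optional `origin_mm`), `background_ac`, `lesions` (path to a
#' lesion CSV) or `n_lesions` + `lesion_seed`, `ref_scanner` / `test_scanner`
#' (`name`, `spacing_mm`, `resolution_fwhm_mm`, `pgc_factor`, `noise_coeff`,
#' `emission_time_min`), `scan_seeds` (`ref`, `test`), `target`
#' (`fwhm_mm`, `spacing_mm`), quantification options, and an optional `tiac`
#' block. Missing keys fall back to the [study_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$grid)) {
    args$grid <- pet_grid(unlist(y$grid$shape), unlist(y$grid$spacing_mm),
                          origin = unlist(y$grid$origin_mm %||% c(0, 0, 0)))
  }
  scan_args <- function(s) {
    scanner_model(s$name %||% "scanner", unlist(s$spacing_mm),
                  s$resolution_fwhm_mm, s$pgc_factor %||% 1,
                  s$noise_coeff %||% 0, s$emission_time_min %||% NA_real_)
  }
  if (!is.null(y$ref_scanner)) args$ref_scanner <- scan_args(y$ref_scanner)
  if (!is.null(y$test_scanner)) args$test_scanner <- scan_args(y$test_scanner)
  if (!is.null(y$lesions)) {
    args$lesions <- validate_lesions(readr::read_csv(
      file.path(dirname(path), y$lesions), show_col_types = FALSE))
  }
  if (!is.null(y$scan_seeds)) args$scan_seeds <- unlist(y$scan_seeds)
  if (!is.null(y$target)) {
    args$target <- harmonization_target(y$target$fwhm_mm %||% 7.0,
                                        unlist(y$target$spacing_mm %||% c(2.1, 2.1, 2.4)))
  }
  for (k in c("background_ac", "n_lesions", "lesion_seed", "search_radius",
              "voi_diameter", "exclusion_threshold", "mean_limit", "sd_limit")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$tiac)) {
    args$tiac <- list(rel_sd_levels = unlist(y$tiac$rel_sd_levels),
                      t_eff_list = unlist(y$tiac$t_eff_list),
                      n_draws = y$tiac$n_draws %||% 1e5,
                      seed = y$tiac$seed %||% 7)
  } else if (isFALSE(y$run_tiac)) {
    args$tiac <- NULL
  }
  do.call(study_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# common comparison grid: target spacing over the intersection of the two
# observed extents, so every target voxel center is interior to both
common_target_grid <- function(vol_a, vol_b, target) {
  ea <- grid_extent(vol_grid(vol_a)); eb <- grid_extent(vol_grid(vol_b))
  lo <- pmax(ea["lo", ], eb["lo", ])
  hi <- pmin(ea["hi", ], eb["hi", ])
  span <- hi - lo
  shape <- pmax(floor(span / target$target_spacing + 1e-9) + 1L, 1L)
  pet_grid(shape, target$target_spacing, origin = lo)
}

#' Run the full dual-scanner comparison study
#'
#' Orchestrates phantom generation, scanning by both virtual scanners, the
#' four correction modes (`none`, `pgc`, `harmonization`, `pgc+harmonization`),
#' per-lesion quantification, agreement analysis, and (optionally) the TIAC
#' uncertainty sweep. All four modes are computed from the *same* pair of
#' simulated scans, so the noise realization is identical across modes and
#' the modes are directly comparable. Rerunning with the same config is
#' bit-identical.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, writes `records.csv` (the
#'   fully corrected mode), `summary.json` (all modes, concordance, subgroup
#'   test, acceptance verdicts, provenance), the phantom bundle, and
#'   `tiac_sweep.csv` when the sweep is enabled.
#'
#' @return An object of class `comparison_study`: list with `records` (named
#'   list of per-mode record tibbles), `summaries` (named list of
#'   `ac_agreement` objects), `mode_table` (tibble, one row per mode and AC
#'   type), `tiac` (a `tiac_sweep` tibble or `NULL`), `lesions`, and
#'   `provenance`. `tidy()` returns `mode_table`.
#' @export
run_comparison_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  lesions <- config$lesions
  if (is.null(lesions)) {
    lesions <- sample_lesions(config$n_lesions, config$grid, config$lesion_seed)
  }
  run_stage <- function(stage, lesion_id = NULL, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s'%s failed: %s", stage,
                   if (is.null(lesion_id)) "" else paste0(" (lesion ", lesion_id, ")"),
                   conditionMessage(e)), call. = FALSE)
    })
  }
  truth <- run_stage("phantom", expr =
    build_ground_truth(lesions, config$background_ac, config$grid))
  obs_ref <- run_stage("scan(ref)", expr =
    simulate_scan(truth, config$ref_scanner, config$scan_seeds[["ref"]]))
  obs_test <- run_stage("scan(test)", expr =
    simulate_scan(truth, config$test_scanner, config$scan_seeds[["test"]]))
  tgrid <- common_target_grid(obs_ref, obs_test, config$target)

  mode_volumes <- list(
    none = list(ref = obs_ref, test = obs_test),
    pgc = list(ref = pgc_correct(obs_ref, config$ref_scanner$pgc_factor),
               test = pgc_correct(obs_test, config$test_scanner$pgc_factor)),
    harmonization = list(
      ref = harmonize_volume(obs_ref, config$ref_scanner, config$target,
                             target_grid = tgrid, apply_pgc = FALSE),
      test = harmonize_volume(obs_test, config$test_scanner, config$target,
                              target_grid = tgrid, apply_pgc = FALSE)
    )
  )
  # full mode reuses the harmonized volumes: PGC scaling commutes with the
  # spatial stages, so dividing them is exact and saves two smoothing passes
  mode_volumes[["pgc+harmonization"]] <- list(
    ref = pgc_correct(mode_volumes$harmonization$ref, config$ref_scanner$pgc_factor),
    test = pgc_correct(mode_volumes$harmonization$test, config$test_scanner$pgc_factor)
  )

  records <- purrr::imap(mode_volumes, function(vols, mode) {
    run_stage(paste0("quantify(", mode, ")"), expr =
      measure_pair(vols$ref, vols$test, lesions,
                   search_radius = config$search_radius,
                   voi_diameter = config$voi_diameter,
                   exclusion_threshold = config$exclusion_threshold))
  })
  summaries <- purrr::imap(records, function(rec, mode) {
    run_stage(paste0("agreement(", mode, ")"), expr =
      summarize_agreement(rec, config$mean_limit, config$sd_limit))
  })
  mode_table <- purrr::imap_dfr(summaries, function(s, mode) {
    dplyr::mutate(dplyr::filter(s$differences, .data$exclusions == "excluded"),
                  mode = mode, .before = 1)
  })
  tiac <- NULL
  if (!is.null(config$tiac)) {
    tiac <- run_stage("tiacsim", expr =
      sweep_tiac_uncertainty(config$tiac$rel_sd_levels, config$tiac$t_eff_list,
                             tiacsim_config(n_draws = config$tiac$n_draws,
                                            seed = config$tiac$seed)))
  }
  provenance <- list(
    seeds = list(lesions = if (is.null(config$lesions)) config$lesion_seed else NULL,
                 ref = config$scan_seeds[["ref"]],
                 test = config$scan_seeds[["test"]],
                 tiac = config$tiac$seed),
    scanners = list(ref = unclass(config$ref_scanner),
                    test = unclass(config$test_scanner)),
    target = unclass(config$target),
    quantify = list(search_radius = config$search_radius,
                    voi_diameter = config$voi_diameter,
                    exclusion_threshold = config$exclusion_threshold),
    limits = c(mean = config$mean_limit, sd = config$sd_limit),
    package_version = as.character(utils::packageVersion("petharm"))
  )
  study <- structure(
    list(records = records, summaries = summaries, mode_table = mode_table,
         tiac = tiac, lesions = lesions, provenance = provenance),
    class = "comparison_study"
  )
  if (!is.null(out_dir)) {
    write_study_outputs(study, truth, list(ref = obs_ref, test = obs_test),
                        config, out_dir)
  }
  study
}

write_study_outputs <- function(study, truth, observed, config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_phantom_bundle(truth, observed, study$lesions, file.path(out_dir, "phantom"),
                       scanners = list(ref = config$ref_scanner,
                                       test = config$test_scanner),
                       seeds = as.list(config$scan_seeds))
  readr::write_csv(study$records[["pgc+harmonization"]],
                   file.path(out_dir, "records.csv"))
  summary_json <- list(
    provenance = study$provenance,
    modes = lapply(study$summaries, function(s) {
      list(differences = s$differences, concordance = s$concordance,
           subgroup = s$subgroup)
    })
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if (!is.null(study$tiac)) {
    readr::write_csv(study$tiac, file.path(out_dir, "tiac_sweep.csv"))
  }
  invisible(out_dir)
}

#' @export
print.comparison_study <- function(x, ...) {
  cat("Dual-scanner comparison study\n")
  cat(sprintf("  %d lesions (%d excluded at low AC)\n", nrow(x$lesions),
              sum(x$records[[1]]$excluded)))
  tb <- x$mode_table
  for (m in unique(tb$mode)) {
    r <- dplyr::filter(tb, .data$mode == m)
    cat(sprintf("  %-19s avg: %6.1f%% +/- %5.1f%% [%s]   max: %6.1f%% +/- %5.1f%% [%s]\n",
                m,
                r$mean[r$ac_type == "avg"], r$sd[r$ac_type == "avg"],
                ifelse(r$accepted[r$ac_type == "avg"], "pass", "FAIL"),
                r$mean[r$ac_type == "max"], r$sd[r$ac_type == "max"],
                ifelse(r$accepted[r$ac_type == "max"], "pass", "FAIL")))
  }
  if (!is.null(x$tiac)) {
    cat(sprintf("  TIAC sweep: %d cells, max rel SD %.1f%% at AC rel SD %.0f%%\n",
                nrow(x$tiac), max(x$tiac$rel_sd_tiac_pct),
                100 * x$tiac$rel_sd_ac[which.max(x$tiac$rel_sd_tiac_pct)]))
  }
  invisible(x)
}

#' Tidy a comparison study
#'
#' @param x A `comparison_study` from [run_comparison_study()].
#' @param ... Unused.
#' @return The mode table: one row per correction mode and AC type with
#'   difference statistics and acceptance flags (low-AC lesions excluded).
#' @exportS3Method generics::tidy
tidy.comparison_study <- function(x, ...) x$mode_table
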