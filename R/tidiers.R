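#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Lin's concordance fit
#'
#' @param x A `ccc` object from [lins_ccc()].
#' @param ... Unused.
#' @return A one-row tibble: `rho_c`, `ci_low`, `ci_high`, `n`,
#'   `mcbride_class`, `pearson_r`, `bias_correction`.
#' @exportS3Method generics::tidy
tidy.ccc <- function(x, ...) {
  tibble::tibble(rho_c = x$rho_c, ci_low = x$ci_low, ci_high = x$ci_high,
                 n = x$n, mcbride_class = x$mcbride_class,
                 pearson_r = x$pearson_r, bias_correction = x$bias_correction)
}

#' @rdname tidy.ccc
#' @exportS3Method generics::glance
glance.ccc <- function(x, ...) tidy.ccc(x)

#' Tidy a TIAC simulation result
#'
#' @param x A `tiacsim_result` from [simulate_tiac_uncertainty()].
#' @param ... Unused.
#' @return A one-row tibble with the simulation inputs and the resulting
#'   relative uncertainties.
#' @exportS3Method generics::tidy
tidy.tiacsim_result <- function(x, ...) {
  tibble::tibble(
    t_eff_h = x$config$t_eff_124, rel_sd_ac = x$config$rel_sd_ac,
    rel_sd_tiac_pct = x$rel_sd_tiac, sd_about_mean_pct = x$sd_about_mean,
    mean_pct_diff = x$mean_pct_diff, tiac_ref = x$tiac_ref,
    n_draws = x$n_draws, n_resampled = x$n_resampled
  )
}

#' Tidy / glance an agreement summary
#'
#' `tidy()` returns the per-AC-type difference statistics (with and without
#' low-AC exclusions) with acceptance flags; `glance()` a one-row overview of
#' the exclusion-filtered analysis.
#'
#' @param x An `ac_agreement` from [summarize_agreement()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ac_agreement <- function(x, ...) x$differences

#' @rdname tidy.ac_agreement
#' @exportS3Method generics::glance
glance.ac_agreement <- function(x, ...) {
  d <- dplyr::filter(x$differences, .data$exclusions == "excluded")
  avg <- dplyr::filter(d, .data$ac_type == "avg")
  mx <- dplyr::filter(d, .data$ac_type == "max")
  cc <- x$concordance
  tibble::tibble(
    n_lesions = nrow(x$records),
    n_excluded = sum(x$records$excluded),
    mean_pct_avg = avg$mean, sd_pct_avg = avg$sd, accepted_avg = avg$accepted,
    mean_pct_max = mx$mean, sd_pct_max = mx$sd, accepted_max = mx$accepted,
    rho_c_avg = cc$rho_c[cc$ac_type == "avg"],
    rho_c_max = cc$rho_c[cc$ac_type == "max"]
  )
}
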