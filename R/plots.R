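#' Plot a TIAC uncertainty sweep
#'
#' One curve per assumed effective ¹²⁴I half-life: relative SD of the
#' projected ¹³¹I TIAC contribution against the relative SD of the ¹²⁴I AC
#' measurements.
#'
#' @param object A `tiac_sweep` tibble from [sweep_tiac_uncertainty()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tiac_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = 100 * .data$rel_sd_ac,
                               y = .data$rel_sd_tiac_pct,
                               colour = factor(.data$t_eff_h),
                               group = factor(.data$t_eff_h))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "relative SD of ¹²⁴I AC (%)",
                  y = "relative SD of ¹³¹I TIAC contribution (%)",
                  colour = "effective ¹²⁴I\nhalf-life (h)") +
    ggplot2::theme_minimal()
}

#' Plot per-lesion percentage differences against reference AC
#'
#' Scatter of the percentage deviation of test from reference AC as a
#' function of the reference AC (log scale), with the zero line and the
#' ±25% precision band; excluded low-AC lesions are hollow.
#'
#' @param object An `ac_agreement` from [summarize_agreement()].
#' @param ac_type `"avg"` or `"max"`.
#' @param band Half-width of the reference band, percentage points.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ac_agreement <- function(object, ac_type = c("avg", "max"), band = 25, ...) {
  ac_type <- match.arg(ac_type)
  df <- dplyr::mutate(object$records,
                      pct = .data[[paste0("pct_diff_", ac_type)]],
                      ref = .data[[paste0("ref_", ac_type, "_ac")]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ref, y = .data$pct,
                                   colour = .data$proximity,
                                   shape = .data$excluded)) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_hline(yintercept = c(-band, band), linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = sprintf("reference (CT-based) %s-AC (kBq/mL)", ac_type),
                  y = sprintf("%s-AC percentage difference (%%)", ac_type),
                  colour = "trachea") +
    ggplot2::theme_minimal()
}

#' Concordance plot of test against reference ACs
#'
#' Paired ACs on the identity-line plot used with Lin's concordance analysis
#' (log-log, with the 45° identity line).
#'
#' @param records A paired-record tibble from [measure_pair()].
#' @param ac_type `"avg"` or `"max"`.
#' @return A ggplot.
#' @export
plot_concordance <- function(records, ac_type = c("avg", "max")) {
  ac_type <- match.arg(ac_type)
  df <- dplyr::mutate(records,
                      ref = .data[[paste0("ref_", ac_type, "_ac")]],
                      test = .data[[paste0("test_", ac_type, "_ac")]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ref, y = .data$test)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("reference %s-AC (kBq/mL)", ac_type),
                  y = sprintf("test %s-AC (kBq/mL)", ac_type)) +
    ggplot2::theme_minimal()
}
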