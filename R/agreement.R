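#' Descriptive statistics of percentage differences
#'
#' The reporting convention for paired-difference data: mean (median) ± SD
#' (minimum to maximum). SD uses the sample (n − 1) denominator; the median
#' of an even n is the midpoint of the two central order statistics.
#'
#' @param values Numeric vector, n >= 2.
#' @return A one-row tibble: `n`, `mean`, `median`, `sd`, `min`, `max`.
#' @export
describe <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("need at least 2 non-missing values (sd undefined otherwise)", call. = FALSE)
  }
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    median = stats::median(values),
    sd = stats::sd(values),
    min = min(values),
    max = max(values)
  )
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement of paired measurements against the identity line,
#' penalizing both imprecision (scatter) and inaccuracy (location/scale shift
#' from the 45° line): `rho_c = 2 * s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)`
#' with population (n-denominator) moments, Lin's original estimator. The
#' two-sided confidence interval is built on the Fisher z scale
#' (`atanh(rho_c)`) with Lin's asymptotic variance and back-transformed.
#' The qualitative strength-of-agreement class follows McBride's bands:
#' almost perfect above 0.99, substantial 0.95–0.99, moderate 0.90–0.95,
#' poor below 0.90.
#'
#' @param x,y Paired measurements (equal length, n >= 3, each with nonzero
#'   variance).
#' @param alpha Two-sided significance level for the CI (default 0.05).
#'
#' @return An object of class `ccc` with fields `rho_c`, `ci_low`, `ci_high`,
#'   `n`, `mcbride_class`, `pearson_r`, `bias_correction` (accuracy factor
#'   `rho_c / r`), and `alpha`. [tidy()] and [glance()] methods return it as
#'   a one-row tibble.
#' @examples
#' fit <- lins_ccc(c(1, 2, 3, 4, 5), c(1.1, 2.2, 2.9, 4.3, 4.8))
#' glance(fit)
#' @export
lins_ccc <- function(x, y, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need n >= 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)            # n-denominator moments (Lin 1989)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 || sy2 == 0) stop("x and y must each have nonzero variance", call. = FALSE)
  rho_c <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  # Lin's asymptotic variance of z = atanh(rho_c)
  u <- (mx - my) / sqrt(sqrt(sx2 * sy2))
  if (abs(rho_c) < 1) {
    var_z <- ((1 - r^2) * rho_c^2 / ((1 - rho_c^2) * r^2) +
                2 * rho_c^3 * (1 - rho_c) * u^2 / (r * (1 - rho_c^2)^2) -
                rho_c^4 * u^4 / (2 * r^2 * (1 - rho_c^2)^2)) / (n - 2)
    z <- atanh(rho_c)
    hw <- stats::qnorm(1 - alpha / 2) * sqrt(max(var_z, 0))
    ci <- tanh(c(z - hw, z + hw))
  } else {
    ci <- c(rho_c, rho_c)            # degenerate perfect concordance
  }
  structure(
    list(rho_c = rho_c, ci_low = ci[1], ci_high = ci[2], n = n,
         mcbride_class = mcbride_class(rho_c), pearson_r = r,
         bias_correction = rho_c / r, alpha = alpha),
    class = "ccc"
  )
}

mcbride_class <- function(rho_c) {
  if (rho_c > 0.99) "almost perfect"
  else if (rho_c >= 0.95) "substantial"
  else if (rho_c >= 0.90) "moderate"
  else "poor"
}

#' @export
print.ccc <- function(x, ...) {
  cat(sprintf("Lin's concordance: rho_c = %.4f (%d%% CI %.4f to %.4f), n = %d — %s\n",
              x$rho_c, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$n,
              x$mcbride_class))
  invisible(x)
}

#' Mann-Whitney U test for two independent groups
#'
#' Rank-sum comparison of two groups (e.g. percentage differences of
#' trachea-adjacent vs distant lesions). The U statistic is reported for the
#' first group; the two-sided p-value is exact (full enumeration of the rank
#' distribution) when both groups are small and untied, and otherwise uses
#' the normal approximation with midrank tie correction and continuity
#' correction.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return A one-row tibble: `u`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            correct = TRUE))
  exact_used <- !grepl("continuity", wt$method) &&
    !anyDuplicated(c(a, b)) && length(a) < 50 && length(b) < 50
  tibble::tibble(
    u = unname(wt$statistic),
    p_value = min(wt$p.value, 1),
    n_a = length(a), n_b = length(b),
    method = if (exact_used) "exact" else "normal approximation"
  )
}

#' Acceptance rule for quantitative agreement
#'
#' Quantitative performance of the test system is acceptable when the mean
#' percentage difference is within ±`mean_limit` (accuracy) *and* the SD of
#' the percentage differences is at most `sd_limit` (precision). Boundaries
#' are inclusive.
#'
#' @param stats A one-row [describe()] tibble (needs `mean` and `sd`).
#' @param mean_limit Accuracy bound, percentage points (default 10).
#' @param sd_limit Precision bound, percentage points (default 25).
#' @return A one-row tibble: `mean_ok`, `sd_ok`, `accepted`.
#' @examples
#' acceptance_check(describe(c(-10, 0, 10)))
#' @export
acceptance_check <- function(stats, mean_limit = 10, sd_limit = 25) {
  stopifnot(all(c("mean", "sd") %in% names(stats)), nrow(stats) == 1L)
  mean_ok <- abs(stats$mean) <= mean_limit
  sd_ok <- stats$sd <= sd_limit
  tibble::tibble(mean_ok = mean_ok, sd_ok = sd_ok, accepted = mean_ok && sd_ok)
}

#' Full agreement summary of paired lesion records
#'
#' The machine-readable twin of a scanner-agreement results section: for each
#' AC type (max-AC and 7-mm-sphere avg-AC), descriptive statistics of the
#' percentage differences with and without the low-AC exclusions, Lin's
#' concordance on the retained pairs, the acceptance verdict, and the
#' Mann-Whitney comparison of trachea-adjacent vs distant lesions (per AC
#' type, on retained lesions).
#'
#' @param records A paired-record tibble from [measure_pair()] (columns
#'   `pct_diff_max`, `pct_diff_avg`, `ref_*`/`test_*` ACs, `proximity`,
#'   `excluded`).
#' @param mean_limit,sd_limit Acceptance bounds, percentage points.
#' @param alpha CI significance level for Lin's concordance.
#'
#' @return An object of class `ac_agreement`: a list with tibbles
#'   `differences` (per AC type and exclusion handling), `concordance`,
#'   `subgroup`, and the input `records`. `tidy()` returns the `differences`
#'   table; `glance()` a one-row overview.
#' @export
summarize_agreement <- function(records, mean_limit = 10, sd_limit = 25,
                                alpha = 0.05) {
  stopifnot(all(c("pct_diff_max", "pct_diff_avg", "excluded") %in% names(records)))
  kept <- dplyr::filter(records, !.data$excluded)
  if (nrow(kept) < 3L) stop("need at least 3 retained lesions", call. = FALSE)

  one_mode <- function(df, ac_type, exclusions) {
    v <- df[[paste0("pct_diff_", ac_type)]]
    st <- describe(v)
    dplyr::bind_cols(
      tibble::tibble(ac_type = ac_type, exclusions = exclusions),
      st, acceptance_check(st, mean_limit, sd_limit)
    )
  }
  differences <- dplyr::bind_rows(
    one_mode(kept, "avg", "excluded"),
    one_mode(kept, "max", "excluded"),
    one_mode(records, "avg", "all"),
    one_mode(records, "max", "all")
  )
  concordance <- dplyr::bind_rows(
    dplyr::mutate(glance(lins_ccc(kept$ref_avg_ac, kept$test_avg_ac, alpha)),
                  ac_type = "avg", .before = 1),
    dplyr::mutate(glance(lins_ccc(kept$ref_max_ac, kept$test_max_ac, alpha)),
                  ac_type = "max", .before = 1)
  )
  subgroup <- purrr::map_dfr(c(avg = "avg", max = "max"), function(ac_type) {
    v <- kept[[paste0("pct_diff_", ac_type)]]
    adj <- v[kept$proximity == "adjacent"]
    dis <- v[kept$proximity == "distant"]
    if (length(adj) == 0L || length(dis) == 0L) {
      return(tibble::tibble(ac_type = ac_type, u = NA_real_, p_value = NA_real_,
                            n_a = length(adj), n_b = length(dis),
                            method = "not run (empty group)"))
    }
    dplyr::mutate(mann_whitney(adj, dis), ac_type = ac_type, .before = 1)
  })
  structure(
    list(differences = differences, concordance = concordance,
         subgroup = subgroup, records = records,
         limits = c(mean = mean_limit, sd = sd_limit)),
    class = "ac_agreement"
  )
}

#' @export
print.ac_agreement <- function(x, ...) {
  cat("Scanner agreement summary\n")
  cat(sprintf("  lesions: %d (%d excluded at low AC)\n",
              nrow(x$records), sum(x$records$excluded)))
  d <- dplyr::filter(x$differences, .data$exclusions == "excluded")
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %s-AC: %.0f%% (%.0f%%) +/- %.0f%% (%.0f to %.0f%%) — %s\n",
                d$ac_type[i], d$mean[i], d$median[i], d$sd[i], d$min[i], d$max[i],
                ifelse(d$accepted[i], "accepted", "rejected")))
  }
  for (i in seq_len(nrow(x$concordance))) {
    cc <- x$concordance[i, ]
    cat(sprintf("  Lin's rho_c (%s-AC): %.3f (%.3f to %.3f) — %s\n",
                cc$ac_type, cc$rho_c, cc$ci_low, cc$ci_high, cc$mcbride_class))
  }
  invisible(x)
}
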