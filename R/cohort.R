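#' Coefficient of variability
#'
#' Intraindividual variability index: the sample (n-1) standard deviation as
#' a percentage of the mean.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @param patient_id Optional identifier carried into the result.
#' @return A list with `patient_id`, `mean`, `sd` and `cov_percent`.
#' @export
#' @examples
#' coefficient_of_variability(c(10, 20, 30, 40)) # CoV 51.64%
coefficient_of_variability <- function(values, patient_id = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("coefficient of variability needs at least 2 values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) {
    stop("coefficient of variability is undefined for zero mean",
         call. = FALSE)
  }
  s <- stats::sd(values)
  list(patient_id = patient_id, mean = m, sd = s,
       cov_percent = 100 * s / m)
}

#' Median and interquartile range summary
#'
#' Cohort descriptive summary: median and 25th/75th percentiles, computed
#' with linear interpolation between order statistics (R quantile type 7), so
#' reported IQRs are reproducible bit-for-bit.
#'
#' @param values Numeric vector, length >= 1.
#' @param name Variable name carried into the result.
#' @return A one-row tibble: `variable`, `median`, `iqr_low`, `iqr_high`,
#'   `n`.
#' @export
#' @examples
#' cohort_summary(1:5, "example") # median 3, IQR [2, 4]
cohort_summary <- function(values, name = "value") {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 1) {
    stop("cohort_summary needs at least 1 finite value", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(variable = name, median = q[2], iqr_low = q[1],
                 iqr_high = q[3], n = length(values))
}

#' Percent change relative to the low-PEEP state
#'
#' PEEP-induced percent change of an index, with the low-PEEP value as the
#' reference (comparator) state: `100 * (high - low) / low`.
#'
#' @param value_high_peep,value_low_peep Index values at the high and low
#'   PEEP states; the reference must be nonzero.
#' @return Percent change (vectorized).
#' @export
#' @examples
#' percent_change(0.21, 0.30) # -30
percent_change <- function(value_high_peep, value_low_peep) {
  if (any(value_low_peep == 0)) {
    stop("percent change is undefined for a zero reference value",
         call. = FALSE)
  }
  100 * (value_high_peep - value_low_peep) / value_low_peep
}

#' Pearson correlation with regression slope
#'
#' Pearson's r together with the ordinary least-squares slope of y on x and
#' its 95% confidence interval from the t distribution at n - 2 degrees of
#' freedom. Reported descriptively (no p-value): the per-patient quantities
#' entering these correlations share measured components, so independence
#' assumptions do not hold.
#'
#' @param xs,ys Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @param x_name,y_name Labels carried into the result.
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return A one-row tibble: `x_name`, `y_name`, `r`, `slope`,
#'   `slope_ci_low`, `slope_ci_high`, `n`.
#' @export
#' @examples
#' correlate(1:10, 2 * (1:10) + 1) # r = 1, slope = 2
correlate <- function(xs, ys, x_name = "x", y_name = "y",
                      conf_level = 0.95) {
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]
  ys <- ys[keep]
  n <- length(xs)
  if (n < 3 || length(ys) != n) {
    stop("correlate needs >= 3 complete pairs", call. = FALSE)
  }
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- stats::cor(xs, ys)
  fit <- stats::lm(ys ~ xs)
  slope <- unname(stats::coef(fit)[2])
  se <- sqrt(sum(stats::residuals(fit)^2) / (n - 2) /
               sum((xs - mean(xs))^2))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  tibble::tibble(x_name = x_name, y_name = y_name, r = r, slope = slope,
                 slope_ci_low = slope - tcrit * se,
                 slope_ci_high = slope + tcrit * se, n = n)
}

#' Cohort correlation endpoints
#'
#' Assembles the headline endpoint set from an analyzed cohort (see
#' [analyze_cohort()]): the global R/I ratio against the PEEP-induced percent
#' change (highest versus lowest trial PEEP) in dynamic, static and total
#' strain; the granular R/I ratio against the per-range strain changes,
#' pooled across patients and narrow ranges; the mean narrow-range R/I
#' against the global R/I; and the mean narrow-range Crec against the global
#' Crec.
#'
#' @param cohort An `recrin_cohort` object from [analyze_cohort()].
#' @return A tibble with one row per endpoint (see [correlate()]); endpoints
#'   whose inputs are degenerate (zero variance, < 3 pairs) are reported with
#'   `r = NA` and the failure message in `note`.
#' @export
endpoint_table <- function(cohort) {
  stopifnot(inherits(cohort, "recrin_cohort"))
  per <- cohort$patients
  if (length(per) < 3) {
    stop("endpoint correlations need at least 3 analyzed patients",
         call. = FALSE)
  }

  global <- dplyr::bind_rows(lapply(per, function(p) {
    st <- p$strain
    hi <- st[which.max(st$peep), ]
    lo_peep <- min(st$peep[st$peep > 0])
    lo <- st[st$peep == lo_peep, ]
    narrow <- p$ranges[!p$ranges$crs_substituted, ]
    tibble::tibble(
      patient_id = p$trial$patient_id,
      global_ri = p$global$ri_ratio,
      global_crec = p$global$crec,
      mean_granular_ri = mean(narrow$ri_ratio),
      mean_granular_crec = mean(narrow$crec),
      d_dynamic = percent_change(hi$dynamic_strain, lo$dynamic_strain),
      d_static = if (lo$static_strain != 0) {
        percent_change(hi$static_strain, lo$static_strain)
      } else NA_real_,
      d_total = percent_change(hi$total_strain, lo$total_strain)
    )
  }))

  granular <- dplyr::bind_rows(lapply(per, function(p) {
    st <- p$strain
    rg <- p$ranges
    dplyr::bind_rows(lapply(seq_len(nrow(rg)), function(i) {
      hi <- st[st$peep == rg$peep_high[i], ]
      lo <- st[st$peep == rg$peep_low[i], ]
      if (nrow(hi) != 1 || nrow(lo) != 1) return(NULL)
      tibble::tibble(
        patient_id = p$trial$patient_id,
        ri_ratio = rg$ri_ratio[i],
        d_dynamic = percent_change(hi$dynamic_strain, lo$dynamic_strain),
        d_static = if (lo$static_strain != 0) {
          percent_change(hi$static_strain, lo$static_strain)
        } else NA_real_,
        d_total = percent_change(hi$total_strain, lo$total_strain)
      )
    }))
  }))

  try_endpoint <- function(xs, ys, x_name, y_name) {
    out <- tryCatch(correlate(xs, ys, x_name, y_name),
                    error = function(e) {
                      tibble::tibble(x_name = x_name, y_name = y_name,
                                     r = NA_real_, slope = NA_real_,
                                     slope_ci_low = NA_real_,
                                     slope_ci_high = NA_real_,
                                     n = sum(is.finite(xs) & is.finite(ys)),
                                     note = conditionMessage(e))
                    })
    if (!"note" %in% names(out)) out$note <- ""
    out
  }

  dplyr::bind_rows(
    try_endpoint(global$global_ri, global$d_dynamic,
                 "global_ri", "pct_change_dynamic_strain"),
    try_endpoint(global$global_ri, global$d_static,
                 "global_ri", "pct_change_static_strain"),
    try_endpoint(global$global_ri, global$d_total,
                 "global_ri", "pct_change_total_strain"),
    try_endpoint(granular$ri_ratio, granular$d_dynamic,
                 "granular_ri", "pct_change_dynamic_strain"),
    try_endpoint(granular$ri_ratio, granular$d_static,
                 "granular_ri", "pct_change_static_strain"),
    try_endpoint(granular$ri_ratio, granular$d_total,
                 "granular_ri", "pct_change_total_strain"),
    try_endpoint(global$mean_granular_ri, global$global_ri,
                 "mean_granular_ri", "global_ri"),
    try_endpoint(global$mean_granular_crec, global$global_crec,
                 "mean_granular_crec", "global_crec")
  )
}
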