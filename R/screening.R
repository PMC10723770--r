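#' Validate an EELV wash-out/wash-in pair
#'
#' The nitrogen-dilution EELV measurement produces a wash-out and a wash-in
#' value; the pair is accepted when the two agree to within 20% of their mean
#' (manufacturer cutoff). The value carried downstream is the pair mean.
#'
#' @param washout,washin EELV values (ml), both > 0.
#' @return A list with `valid` (logical), `mean_eelv` (ml) and
#'   `relative_difference` (fraction of the mean).
#' @export
#' @examples
#' validate_eelv_pair(1550, 1450) # valid, 6.7% apart
#' validate_eelv_pair(1800, 1400) # invalid, 25% apart
validate_eelv_pair <- function(washout, washin) {
  if (!is.finite(washout) || washout <= 0 ||
      !is.finite(washin) || washin <= 0) {
    stop("EELV wash values must be > 0", call. = FALSE)
  }
  mean_eelv <- (washout + washin) / 2
  relative_difference <- abs(washout - washin) / mean_eelv
  list(valid = relative_difference < 0.20,
       mean_eelv = mean_eelv,
       relative_difference = relative_difference)
}

#' Detect the airway opening pressure on a low-flow inflation curve
#'
#' Fits a continuous two-segment piecewise-linear model to the
#' pressure-volume samples by least squares, trying every interior sample
#' pressure as the candidate breakpoint. Airway closure is called when the
#' slope below the best breakpoint is less than 10% of the slope above it; the
#' breakpoint pressure is then the airway opening pressure (AOP). Without
#' closure the function returns 0.
#'
#' @param curve A [low_flow_curve()] (>= 10 samples).
#' @param slope_ratio Closure rule: first-segment slope must be below
#'   `slope_ratio` times the second-segment slope (default 0.1).
#' @return AOP in cm H2O (0 when no closure is detected).
#' @export
detect_airway_opening_pressure <- function(curve, slope_ratio = 0.1) {
  if (nrow(curve) < 10) {
    stop("airway opening pressure detection needs at least 10 samples",
         call. = FALSE)
  }
  p <- curve$pressure
  v <- curve$volume
  n <- length(p)
  # candidate breakpoints: interior sample pressures, leaving >= 2 points per
  # segment so both slopes are identified
  cands <- p[3:(n - 2)]
  best <- NULL
  for (bp in cands) {
    # continuous hinge model: v = a + s1 * (p - bp) + (s2 - s1) * max(p - bp, 0)
    x1 <- p - bp
    x2 <- pmax(p - bp, 0)
    fit <- stats::lm.fit(cbind(1, x1, x2), v)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse) {
      s1 <- fit$coefficients[2]
      s2 <- fit$coefficients[2] + fit$coefficients[3]
      best <- list(bp = bp, sse = sse, s1 = s1, s2 = s2)
    }
  }
  closed <- is.finite(best$s2) && best$s2 > 0 &&
    best$s1 < slope_ratio * best$s2
  if (closed) best$bp else 0
}

#' Screen a trial for eligibility
#'
#' Applies the study eligibility screens: intrinsic PEEP greater than
#' 2 cm H2O, and airway closure with an airway opening pressure greater than
#' 5 cm H2O on the low-flow inflation curve. A screen whose input is absent is
#' skipped (recorded in `skipped`), never treated as a failure.
#'
#' @param trial A [patient_trial()].
#' @return A list with `eligible` (TRUE iff `reasons` is empty), `reasons`
#'   (character vector drawn from `"INTRINSIC_PEEP"`, `"AIRWAY_CLOSURE"`),
#'   `airway_opening_pressure` (NA when no curve was provided) and `skipped`
#'   (screens not performed for lack of data).
#' @export
screen_trial <- function(trial) {
  stopifnot(inherits(trial, "patient_trial"))
  reasons <- character()
  skipped <- character()
  if (is.null(trial$intrinsic_peep)) {
    skipped <- c(skipped, "INTRINSIC_PEEP")
  } else if (trial$intrinsic_peep > 2) {
    reasons <- c(reasons, "INTRINSIC_PEEP")
  }
  aop <- NA_real_
  if (is.null(trial$low_flow)) {
    skipped <- c(skipped, "AIRWAY_CLOSURE")
  } else {
    aop <- detect_airway_opening_pressure(trial$low_flow)
    if (aop > 5) reasons <- c(reasons, "AIRWAY_CLOSURE")
  }
  list(eligible = length(reasons) == 0,
       reasons = reasons,
       airway_opening_pressure = aop,
       skipped = skipped)
}
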