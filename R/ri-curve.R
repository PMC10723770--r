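#' Fit the origin-constrained quadratic R/I versus PEEP model
#'
#' Models the recruitment-to-inflation ratio as `RI(P) = b1*P + b2*P^2`, a
#' parabola constrained through (0, 0): there is no recruitment at zero PEEP.
#' Although often described as a nonlinear regression, the constrained model
#' is linear in `(b1, b2)`, so the weighted least-squares minimizer of
#' `sum(((ri - b1*P - b2*P^2) / sigma)^2)` is obtained in closed form from the
#' normal equations on the basis `{P, P^2}` — the same minimizer an iterative
#' nonlinear optimizer would converge to, without convergence ambiguity. When
#' a full error covariance of the points is supplied the fit generalizes to
#' GLS, `argmin (ri - X b)' W (ri - X b)` with `W = solve(covariance)`.
#'
#' The chi-square statistic is the weighted residual sum at the minimizer,
#' referred to a chi-square distribution with `n - 2` degrees of freedom; the
#' fit passes the goodness-of-fit gate when the upper-tail probability is at
#' least `gof_alpha`. `r_squared` is computed against the zero-intercept null
#' (the model that predicts 0 everywhere, the natural null for a curve
#' constrained through the origin): `1 - chi2 / (y' W y)`.
#'
#' Shape classification: `"saturating"` when `b2 < 0` and the vertex
#' `-b1 / (2 b2)` lies within the observed mid-PEEP range extended by
#' `range_extension`; `"ever_increasing"` when `b2 >= 0` or the vertex lies
#' beyond that bound; `"indeterminate"` when the goodness-of-fit gate fails.
#' A fit is flagged `implausible` when the vertex exceeds
#' `implausibility_bound` (default 20 cm H2O) or the predicted |R/I| exceeds
#' that bound anywhere on `[0, extrapolation_max]` — extreme estimates that
#' should not be used for prediction.
#'
#' @param points Data frame with columns `mid_peep`, `ri_ratio` and
#'   optionally `sigma` (per-point standard deviation; default 1, i.e.
#'   unweighted). At least 3 points with distinct `mid_peep`.
#' @param covariance Optional full error covariance matrix of the points
#'   (overrides `sigma`); use [ri_point_covariance()] for the propagated
#'   EELV-noise covariance.
#' @param gof_alpha Goodness-of-fit significance level (default 0.05).
#' @param implausibility_bound Implausibility threshold on the vertex
#'   location and on |predicted R/I| (default 20).
#' @param extrapolation_max Upper end of the PEEP interval over which
#'   predictions are considered meaningful (default 20 cm H2O).
#' @param range_extension How far beyond the largest mid-PEEP the vertex may
#'   lie and still count as saturating; default: the largest gap between
#'   consecutive mid-PEEPs.
#' @return An object of class `ri_curve_fit`: `b1`, `b2`, `coef_cov`,
#'   `r_squared`, `chi_square`, `gof_df`, `gof_p`, `gof_pass`, `vertex_peep`
#'   (NA unless `b2 < 0`), `shape`, `implausible`, `n`, `points` and the
#'   gating constants used.
#' @export
#' @examples
#' p <- c(2.5, 6.5, 9, 11.5, 14)
#' fit_ri_curve(data.frame(mid_peep = p, ri_ratio = 0.3 * p - 0.01 * p^2))
fit_ri_curve <- function(points, covariance = NULL, gof_alpha = 0.05,
                         implausibility_bound = 20, extrapolation_max = 20,
                         range_extension = NULL) {
  points <- as.data.frame(points)
  if (!all(c("mid_peep", "ri_ratio") %in% names(points))) {
    stop("points must have columns mid_peep and ri_ratio", call. = FALSE)
  }
  n <- nrow(points)
  if (n < 3) {
    stop("at least 3 points are required to fit the R/I curve",
         call. = FALSE)
  }
  x <- points$mid_peep
  y <- points$ri_ratio
  if (length(unique(x)) < 2) {
    stop("all mid_peep values are identical: singular design", call. = FALSE)
  }
  if (is.null(points$sigma)) points$sigma <- 1
  if (any(points$sigma <= 0)) stop("sigma must be > 0", call. = FALSE)

  X <- cbind(x, x^2)
  if (is.null(covariance)) {
    W <- diag(1 / points$sigma^2, n)
  } else {
    stopifnot(is.matrix(covariance), all(dim(covariance) == n))
    W <- solve(covariance)
  }
  XtW <- crossprod(X, W)
  A <- XtW %*% X
  if (rcond(A) < 1e-12) {
    stop("singular design in the R/I fit", call. = FALSE)
  }
  beta <- solve(A, XtW %*% y)
  b1 <- beta[1]
  b2 <- beta[2]
  # round-off guard: an exactly linear law fits with |b2| at machine noise
  if (abs(b2) < 1e-12 * max(1, abs(b1))) b2 <- 0
  res <- y - drop(X %*% beta)
  chi2 <- drop(crossprod(res, W %*% res))
  sstot <- drop(crossprod(y, W %*% y))
  r2 <- if (sstot > 0) 1 - chi2 / sstot else NA_real_
  df <- n - 2
  gof_p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  gof_pass <- gof_p >= gof_alpha

  vertex <- if (b2 < 0) -b1 / (2 * b2) else NA_real_
  if (is.null(range_extension)) {
    range_extension <- max(diff(sort(unique(x))))
  }
  # extreme of the parabola on [0, extrapolation_max], plus the endpoint
  cand <- extrapolation_max
  if (!is.na(vertex) && vertex >= 0 && vertex <= extrapolation_max) {
    cand <- c(cand, vertex)
  }
  if (b2 > 0) {
    minimum <- -b1 / (2 * b2)
    if (minimum >= 0 && minimum <= extrapolation_max) cand <- c(cand, minimum)
  }
  max_abs_ri <- max(abs(b1 * cand + b2 * cand^2))
  implausible <- (!is.na(vertex) && vertex > implausibility_bound) ||
    max_abs_ri > implausibility_bound

  shape <- if (!gof_pass) {
    "indeterminate"
  } else if (b2 < 0 && !is.na(vertex) && vertex <= max(x) + range_extension) {
    "saturating"
  } else {
    "ever_increasing"
  }

  structure(
    list(b1 = b1, b2 = b2,
         coef_cov = solve(A),
         r_squared = r2,
         chi_square = chi2, gof_df = df, gof_p = gof_p, gof_pass = gof_pass,
         vertex_peep = vertex, shape = shape, implausible = implausible,
         n = n, points = points,
         gof_alpha = gof_alpha,
         implausibility_bound = implausibility_bound,
         extrapolation_max = extrapolation_max),
    class = "ri_curve_fit"
  )
}

#' @export
print.ri_curve_fit <- function(x, ...) {
  cat(sprintf("<ri_curve_fit> RI(P) = %.4g P %+.4g P^2 on %d points\n",
              x$b1, x$b2, x$n))
  cat(sprintf("  R^2 = %.4f; chi2 = %.3f (df %d, p = %.3f) -> GoF %s\n",
              x$r_squared, x$chi_square, x$gof_df, x$gof_p,
              if (x$gof_pass) "pass" else "FAIL"))
  cat(sprintf("  shape: %s; vertex: %s cm H2O; implausible: %s\n",
              x$shape,
              if (is.na(x$vertex_peep)) "none" else
                sprintf("%.1f", x$vertex_peep),
              x$implausible))
  invisible(x)
}

#' Usability gate for an R/I curve fit
#'
#' A fit is usable for PEEP prediction only when it passes the chi-square
#' goodness-of-fit test and is not flagged implausible; the gate objectively
#' excludes patients in whom the maneuver delivered unreliable data.
#'
#' @param fit An [fit_ri_curve()] result.
#' @return A list with `usable` (logical) and `reason` (empty string when
#'   usable; otherwise `"GOF_FAIL"`, `"IMPLAUSIBLE"` or both, comma-joined).
#' @export
gof_gate <- function(fit) {
  stopifnot(inherits(fit, "ri_curve_fit"))
  reasons <- character()
  if (!fit$gof_pass) reasons <- c(reasons, "GOF_FAIL")
  if (fit$implausible) reasons <- c(reasons, "IMPLAUSIBLE")
  list(usable = length(reasons) == 0,
       reason = paste(reasons, collapse = ","))
}

#' Predict the R/I ratio at a PEEP level
#'
#' Evaluates the fitted parabola `b1*peep + b2*peep^2`. Refuses to predict
#' from a fit that fails the usability gate, or outside the configured
#' interval `[0, extrapolation_max]`.
#'
#' @param fit An [fit_ri_curve()] result.
#' @param peep PEEP level(s), cm H2O.
#' @return Predicted R/I ratio(s); exactly 0 at `peep = 0`.
#' @export
predict_ri <- function(fit, peep) {
  stopifnot(inherits(fit, "ri_curve_fit"))
  gate <- gof_gate(fit)
  if (!gate$usable) {
    stop(sprintf("refusing to predict from an unusable fit (%s)",
                 gate$reason), call. = FALSE)
  }
  if (any(peep < 0 | peep > fit$extrapolation_max)) {
    stop(sprintf("prediction outside the supported PEEP interval [0, %g]",
                 fit$extrapolation_max), call. = FALSE)
  }
  fit$b1 * peep + fit$b2 * peep^2
}

#' Propagated uncertainty of granular R/I points
#'
#' Propagates a single EELV measurement standard deviation through the
#' recruited-volume chain. The EELV used at each step is the mean of two
#' independent wash draws (variance `sd^2 / 2`), so the PEEP volume of a
#' range carries variance `sd^2`; the single-breath released volume of the
#' 5-to-0 range carries `sd^2` as well. Dividing by `delta_peep * crs_low`
#' gives the per-point R/I standard deviation `sd / (delta_peep * crs_low)`.
#'
#' @param ranges Granular range tibble from
#'   [compute_granular_recruitment()].
#' @param eelv_sd EELV measurement standard deviation per wash draw (ml).
#' @return Numeric vector of per-point standard deviations.
#' @export
ri_point_sigma <- function(ranges, eelv_sd) {
  if (eelv_sd <= 0) {
    stop("eelv_sd must be > 0 for uncertainty propagation", call. = FALSE)
  }
  eelv_sd / (ranges$delta_peep * ranges$crs_low)
}

#' Propagated covariance of granular R/I points
#'
#' Adjacent ranges of the ladder share the EELV measured at their common PEEP
#' step, so their propagated R/I errors are negatively correlated:
#' `cov = -sd^2/2 / (delta_i * crs_i * delta_j * crs_j)` when ranges i and j
#' share a step node. The 5-to-0 range is built from the independent
#' single-breath volume and shares no node. Supplying this matrix to
#' [fit_ri_curve()] yields the generalized-least-squares fit whose chi-square
#' statistic is correctly calibrated under the propagation model.
#'
#' @inheritParams ri_point_sigma
#' @return A symmetric covariance matrix (one row/column per range).
#' @export
ri_point_covariance <- function(ranges, eelv_sd) {
  if (eelv_sd <= 0) {
    stop("eelv_sd must be > 0 for uncertainty propagation", call. = FALSE)
  }
  n <- nrow(ranges)
  scale <- 1 / (ranges$delta_peep * ranges$crs_low)
  node_var <- eelv_sd^2 / 2  # variance of a wash-pair mean
  # node labels; the zeep range uses the independent single-breath volume
  hi <- ifelse(ranges$crs_substituted, NA_real_, ranges$peep_high)
  lo <- ifelse(ranges$crs_substituted, NA_real_, ranges$peep_low)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        V[i, j] <- eelv_sd^2
      } else {
        shared <- sum(c(
          isTRUE(hi[i] == hi[j]), isTRUE(lo[i] == lo[j]))) -
          sum(c(isTRUE(hi[i] == lo[j]), isTRUE(lo[i] == hi[j])))
        V[i, j] <- shared * node_var
      }
    }
  }
  V * tcrossprod(scale)
}
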