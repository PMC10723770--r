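#' Build one PEEP-step record
#'
#' One plateau of a decremental PEEP trial: the pressures, tidal volume and
#' the end-expiratory lung volume (EELV) wash-out/wash-in pair measured at the
#' end of the step.
#'
#' @param set_peep Set PEEP (cm H2O), >= 0.
#' @param total_peep Total PEEP measured at the end-expiratory hold (cm H2O).
#' @param plateau_pressure Plateau pressure at the end-inspiratory hold
#'   (cm H2O); must exceed `total_peep`.
#' @param tidal_volume Tidal volume (ml), > 0.
#' @param eelv_washout,eelv_washin EELV by nitrogen wash-out / wash-in (ml),
#'   both > 0.
#' @return A one-row tibble with the six step fields.
#' @export
#' @examples
#' peep_step(15, 15, 25.5, 420, 2400, 2420)
peep_step <- function(set_peep, total_peep, plateau_pressure, tidal_volume,
                      eelv_washout, eelv_washin) {
  step <- tibble::tibble(
    set_peep = as.numeric(set_peep),
    total_peep = as.numeric(total_peep),
    plateau_pressure = as.numeric(plateau_pressure),
    tidal_volume = as.numeric(tidal_volume),
    eelv_washout = as.numeric(eelv_washout),
    eelv_washin = as.numeric(eelv_washin)
  )
  validate_steps(step)
  step
}

step_columns <- c(
  "set_peep", "total_peep", "plateau_pressure", "tidal_volume",
  "eelv_washout", "eelv_washin"
)

validate_steps <- function(steps, patient_id = NULL) {
  who <- if (is.null(patient_id)) "" else sprintf(" (patient %s)", patient_id)
  missing_cols <- setdiff(step_columns, names(steps))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing required column(s): %s%s",
                 paste(missing_cols, collapse = ", "), who), call. = FALSE)
  }
  bad <- function(cond, msg) {
    if (any(cond)) stop(paste0(msg, who), call. = FALSE)
  }
  bad(!is.finite(steps$set_peep) | steps$set_peep < 0,
      "set_peep must be finite and >= 0")
  bad(!is.finite(steps$tidal_volume) | steps$tidal_volume <= 0,
      "tidal_volume must be > 0")
  bad(!is.finite(steps$plateau_pressure) |
        steps$plateau_pressure <= steps$total_peep,
      "plateau_pressure must exceed total_peep")
  bad(!is.finite(steps$eelv_washout) | steps$eelv_washout <= 0,
      "eelv_washout must be > 0")
  bad(!is.finite(steps$eelv_washin) | steps$eelv_washin <= 0,
      "eelv_washin must be > 0")
  invisible(steps)
}

#' Build a single-breath derecruitment maneuver record
#'
#' The slow exhalation from PEEP 5 to 0 cm H2O used to measure the lung-volume
#' change attributable to 5 cm H2O of PEEP without ventilating at zero PEEP.
#' The released volume is `exhaled_vt - inspired_vt`.
#'
#' @param inspired_vt Inspired tidal volume of the breath (ml).
#' @param exhaled_vt Exhaled tidal volume of the breath (ml).
#' @param from_peep,to_peep PEEP before/after the maneuver (cm H2O); the
#'   protocol value is 5 to 0.
#' @return An object of class `derecruitment_breath`.
#' @export
derecruitment_breath <- function(inspired_vt, exhaled_vt, from_peep = 5,
                                 to_peep = 0) {
  if (!is.finite(inspired_vt) || inspired_vt <= 0 ||
      !is.finite(exhaled_vt) || exhaled_vt <= 0) {
    stop("derecruitment breath volumes must be > 0", call. = FALSE)
  }
  if (!(from_peep > to_peep)) {
    stop("from_peep must exceed to_peep", call. = FALSE)
  }
  structure(
    list(inspired_vt = as.numeric(inspired_vt),
         exhaled_vt = as.numeric(exhaled_vt),
         from_peep = as.numeric(from_peep),
         to_peep = as.numeric(to_peep)),
    class = "derecruitment_breath"
  )
}

#' Build a low-flow inflation pressure-volume curve
#'
#' Samples of the low-flow (5 l/min) inflation performed after prolonged
#' exhalation at zero PEEP, used to screen for airway closure.
#'
#' @param pressure Airway pressures (cm H2O), strictly increasing, >= 10
#'   samples.
#' @param volume Inflated volumes (ml), non-decreasing.
#' @return A tibble of class `low_flow_curve` with columns `pressure` and
#'   `volume`.
#' @export
low_flow_curve <- function(pressure, volume) {
  if (length(pressure) != length(volume)) {
    stop("pressure and volume must have equal length", call. = FALSE)
  }
  if (length(pressure) < 10) {
    stop("low-flow curve needs at least 10 samples", call. = FALSE)
  }
  if (any(diff(pressure) <= 0)) {
    stop("low-flow pressures must be strictly increasing", call. = FALSE)
  }
  if (any(diff(volume) < 0)) {
    stop("low-flow volumes must be non-decreasing", call. = FALSE)
  }
  out <- tibble::tibble(pressure = as.numeric(pressure),
                        volume = as.numeric(volume))
  class(out) <- c("low_flow_curve", class(out))
  out
}

#' Assemble a patient trial
#'
#' A complete decremental-PEEP-trial record for one patient: the PEEP-step
#' table (ordered by descending set PEEP), plus the optional derecruitment
#' breath, low-flow screening curve, intrinsic PEEP and predicted body weight.
#'
#' @param patient_id Patient identifier (scalar character).
#' @param steps Data frame of PEEP steps (see [peep_step()]); at least 2 rows,
#'   no duplicated `set_peep`. Rows are re-ordered by descending `set_peep`.
#' @param derecruitment Optional [derecruitment_breath()].
#' @param low_flow Optional [low_flow_curve()].
#' @param intrinsic_peep Optional intrinsic PEEP (cm H2O).
#' @param predicted_body_weight Optional predicted body weight (kg).
#' @return An object of class `patient_trial`.
#' @export
#' @examples
#' steps <- do.call(rbind, lapply(c(15, 10, 5), function(p)
#'   peep_step(p, p, p + 10.5, 420, 1500 + 40 * p, 1500 + 40 * p)))
#' patient_trial("P001", steps)
patient_trial <- function(patient_id, steps, derecruitment = NULL,
                          low_flow = NULL, intrinsic_peep = NULL,
                          predicted_body_weight = NULL) {
  if (!is.character(patient_id) || length(patient_id) != 1 ||
      is.na(patient_id) || !nzchar(patient_id)) {
    stop("patient_id must be a non-empty character scalar", call. = FALSE)
  }
  steps <- tibble::as_tibble(steps)[, step_columns]
  validate_steps(steps, patient_id)
  if (nrow(steps) < 2) {
    stop(sprintf("patient %s: a trial needs at least 2 PEEP steps",
                 patient_id), call. = FALSE)
  }
  if (anyDuplicated(steps$set_peep)) {
    stop(sprintf("patient %s: duplicated set_peep values", patient_id),
         call. = FALSE)
  }
  steps <- steps[order(-steps$set_peep), ]
  if (!is.null(derecruitment) &&
      !inherits(derecruitment, "derecruitment_breath")) {
    stop("derecruitment must be a derecruitment_breath", call. = FALSE)
  }
  if (!is.null(low_flow) && !inherits(low_flow, "low_flow_curve")) {
    low_flow <- low_flow_curve(low_flow$pressure, low_flow$volume)
  }
  structure(
    list(patient_id = patient_id,
         predicted_body_weight = predicted_body_weight,
         steps = steps,
         derecruitment = derecruitment,
         low_flow = low_flow,
         intrinsic_peep = intrinsic_peep),
    class = "patient_trial"
  )
}

#' @export
print.patient_trial <- function(x, ...) {
  cat(sprintf("<patient_trial> %s: %d PEEP steps (%s cm H2O)\n",
              x$patient_id, nrow(x$steps),
              paste(x$steps$set_peep, collapse = " > ")))
  cat(sprintf("  derecruitment breath: %s; low-flow curve: %s; intrinsic PEEP: %s\n",
              if (is.null(x$derecruitment)) "absent" else
                sprintf("%.0f ml released", x$derecruitment$exhaled_vt -
                          x$derecruitment$inspired_vt),
              if (is.null(x$low_flow)) "absent" else
                sprintf("%d samples", nrow(x$low_flow)),
              if (is.null(x$intrinsic_peep)) "not measured" else
                format(x$intrinsic_peep)))
  invisible(x)
}

#' @export
print.derecruitment_breath <- function(x, ...) {
  cat(sprintf(
    "<derecruitment_breath> PEEP %g -> %g: inspired %g ml, exhaled %g ml\n",
    x$from_peep, x$to_peep, x$inspired_vt, x$exhaled_vt))
  invisible(x)
}
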