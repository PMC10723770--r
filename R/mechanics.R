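#' Respiratory mechanics of one PEEP step
#'
#' Driving pressure is the plateau pressure minus total PEEP; respiratory
#' system compliance (Crs) is the tidal volume divided by the driving
#' pressure. EELV is the wash-out/wash-in pair mean, and the step is marked
#' invalid when the pair disagrees by 20% or more of the mean.
#'
#' @param step A one-row data frame with the PEEP-step fields (see
#'   [peep_step()]).
#' @return A one-row tibble: `set_peep`, `driving_pressure` (cm H2O), `crs`
#'   (ml/cm H2O), `eelv` (ml), `eelv_relative_difference`, `valid`.
#' @export
#' @examples
#' compute_step_mechanics(peep_step(15, 15, 25, 420, 2400, 2420))
compute_step_mechanics <- function(step) {
  validate_steps(step)
  dp <- step$plateau_pressure - step$total_peep
  if (any(dp <= 0)) {
    stop("plateau pressure must exceed total PEEP (zero/negative driving pressure)",
         call. = FALSE)
  }
  pair <- Map(validate_eelv_pair, step$eelv_washout, step$eelv_washin)
  tibble::tibble(
    set_peep = step$set_peep,
    driving_pressure = dp,
    crs = step$tidal_volume / dp,
    tidal_volume = step$tidal_volume,
    eelv = vapply(pair, `[[`, numeric(1), "mean_eelv"),
    eelv_relative_difference =
      vapply(pair, `[[`, numeric(1), "relative_difference"),
    valid = vapply(pair, `[[`, logical(1), "valid")
  )
}

#' Trial-wide step mechanics
#'
#' Applies [compute_step_mechanics()] to every step of a trial, keeping the
#' descending PEEP order.
#'
#' @param trial A [patient_trial()].
#' @return A tibble with one row per step (descending `set_peep`).
#' @export
trial_mechanics <- function(trial) {
  stopifnot(inherits(trial, "patient_trial"))
  compute_step_mechanics(trial$steps)
}

#' Functional residual capacity from the derecruitment breath
#'
#' The volume released by dropping PEEP from 5 to 0 cm H2O in a single slow
#' breath (`exhaled_vt - inspired_vt`) is the lung volume held by 5 cm H2O of
#' PEEP; subtracting it from the EELV measured at PEEP 5 gives the functional
#' residual capacity (FRC), i.e. the EELV at zero PEEP, without ever
#' ventilating at zero PEEP.
#'
#' @param eelv_peep5 EELV at PEEP 5 cm H2O (ml; wash-pair mean).
#' @param breath A [derecruitment_breath()].
#' @return A list with `peep5_volume` (ml), `frc` (ml) and `flagged`
#'   (TRUE when the released volume is 0, an implausible measurement).
#' @export
#' @examples
#' compute_frc(1500, derecruitment_breath(420, 520))
compute_frc <- function(eelv_peep5, breath) {
  stopifnot(inherits(breath, "derecruitment_breath"))
  if (!isTRUE(all.equal(breath$from_peep, 5)) ||
      !isTRUE(all.equal(breath$to_peep, 0))) {
    warning(sprintf(
      "derecruitment breath is %g -> %g cm H2O, not the protocol 5 -> 0",
      breath$from_peep, breath$to_peep), call. = FALSE)
  }
  peep5_volume <- breath$exhaled_vt - breath$inspired_vt
  if (peep5_volume < 0) {
    stop("exhaled volume below inspired volume: negative release volume",
         call. = FALSE)
  }
  frc <- eelv_peep5 - peep5_volume
  if (frc <= 0) {
    stop("non-positive FRC from the supplied volumes", call. = FALSE)
  }
  list(peep5_volume = peep5_volume, frc = frc, flagged = peep5_volume == 0)
}

range_row <- function(peep_high, peep_low, peep_vol, crs_low, valid,
                      crs_substituted = FALSE) {
  delta <- peep_high - peep_low
  inflation_vol <- delta * crs_low
  v_rec <- peep_vol - inflation_vol
  crec <- v_rec / delta
  tibble::tibble(
    peep_high = peep_high,
    peep_low = peep_low,
    mid_peep = (peep_high + peep_low) / 2,
    delta_peep = delta,
    peep_vol = peep_vol,
    inflation_vol = inflation_vol,
    v_rec = v_rec,
    crec = crec,
    ri_ratio = crec / crs_low,
    crs_low = crs_low,
    crs_substituted = crs_substituted,
    negative_recruitment = v_rec < 0,
    valid = valid
  )
}

#' Recruitment decomposition over one PEEP range
#'
#' Splits the EELV change between two PEEP steps (the PEEP volume) into the
#' inflation predicted from the low-PEEP compliance and the recruited volume:
#' `v_rec = (eelv_high - eelv_low) - (peep_high - peep_low) * crs_low`. The
#' compliance of the recruited lung is `crec = v_rec / delta_peep` and the
#' recruitment-to-inflation ratio is `crec / crs_low`. Negative recruited
#' volumes are retained and flagged, not clipped.
#'
#' @param high,low One-row step-mechanics tibbles (see
#'   [compute_step_mechanics()]); `high$set_peep` must exceed `low$set_peep`.
#' @return A one-row tibble with the range decomposition (`peep_vol`,
#'   `inflation_vol`, `v_rec`, `crec`, `ri_ratio`, `crs_low`, flags).
#' @export
#' @examples
#' h <- tibble::tibble(set_peep = 15, crs = 35, eelv = 2400, valid = TRUE)
#' l <- tibble::tibble(set_peep = 5, crs = 30, eelv = 1900, valid = TRUE)
#' compute_range_recruitment(h, l)
compute_range_recruitment <- function(high, low) {
  if (!(high$set_peep > low$set_peep)) {
    stop("peep_high must exceed peep_low", call. = FALSE)
  }
  range_row(high$set_peep, low$set_peep,
            peep_vol = high$eelv - low$eelv,
            crs_low = low$crs,
            valid = isTRUE(high$valid) && isTRUE(low$valid))
}

#' Granular recruitment across every derecruitment step
#'
#' One [compute_range_recruitment()] per adjacent pair of the decremental
#' ladder, plus (when the derecruitment breath is available and
#' `include_zeep`) the 5-to-0 range, whose PEEP volume is the single-breath
#' released volume and whose low-PEEP compliance is substituted with the Crs
#' measured at PEEP 5 (flagged `crs_substituted`), since the protocol never
#' ventilates at zero PEEP. Ranges touching a step whose EELV pair failed the
#' 20% rule are marked invalid.
#'
#' @param trial A [patient_trial()].
#' @param mechanics Step mechanics from [trial_mechanics()] (computed when
#'   missing).
#' @param frc FRC result from [compute_frc()] (computed when possible and
#'   missing); required for the zero-PEEP range.
#' @param include_zeep Include the 5-to-0 range (default TRUE).
#' @return A tibble of ranges ordered by descending `peep_high`.
#' @export
compute_granular_recruitment <- function(trial, mechanics = NULL, frc = NULL,
                                         include_zeep = TRUE) {
  stopifnot(inherits(trial, "patient_trial"))
  if (is.null(mechanics)) mechanics <- trial_mechanics(trial)
  n <- nrow(mechanics)
  rows <- lapply(seq_len(n - 1), function(i) {
    compute_range_recruitment(mechanics[i, ], mechanics[i + 1, ])
  })
  if (include_zeep && !is.null(trial$derecruitment)) {
    low_step <- mechanics[n, ]
    if (is.null(frc)) frc <- compute_frc(low_step$eelv, trial$derecruitment)
    zeep <- range_row(
      peep_high = trial$derecruitment$from_peep,
      peep_low = trial$derecruitment$to_peep,
      peep_vol = frc$peep5_volume,
      crs_low = low_step$crs,
      valid = isTRUE(low_step$valid),
      crs_substituted = TRUE
    )
    rows <- c(rows, list(zeep))
  }
  dplyr::bind_rows(rows)
}

#' Global recruitment over the full tested PEEP range
#'
#' The same decomposition as [compute_range_recruitment()] applied to the
#' extreme steps of the ladder (highest versus lowest set PEEP).
#'
#' @param mechanics Step mechanics from [trial_mechanics()].
#' @return A one-row range tibble.
#' @export
compute_global_recruitment <- function(mechanics) {
  compute_range_recruitment(mechanics[1, ], mechanics[nrow(mechanics), ])
}

#' Lung strain profile across PEEP levels
#'
#' At each PEEP level (zero PEEP plus every trial step, ascending) the aerated
#' lung volume is the FRC plus the recruitment accumulated from zero PEEP up
#' to that level; dynamic strain is the tidal volume over the aerated volume;
#' static strain is the PEEP-held inflation volume (EELV minus aerated
#' volume, zero at zero PEEP by construction) over the aerated volume; total
#' strain is their sum.
#'
#' @param trial A [patient_trial()].
#' @param ranges Granular ranges from [compute_granular_recruitment()]
#'   (must reach down to PEEP 0 for the cumulative recruitment to be anchored
#'   at zero PEEP).
#' @param frc FRC result from [compute_frc()].
#' @param mechanics Step mechanics from [trial_mechanics()] (computed when
#'   missing).
#' @return A tibble with one row per PEEP level: `peep`, `aerated_volume`,
#'   `cumulative_recruitment`, `cumulative_inflation`, `dynamic_strain`,
#'   `static_strain`, `total_strain`, `valid`.
#' @export
compute_strain_profile <- function(trial, ranges, frc, mechanics = NULL) {
  stopifnot(inherits(trial, "patient_trial"))
  if (is.null(mechanics)) mechanics <- trial_mechanics(trial)
  levels <- sort(unique(c(0, mechanics$set_peep)))
  rows <- lapply(levels, function(p) {
    below <- ranges[ranges$peep_high <= p, ]
    cum_rec <- sum(below$v_rec)
    aerated <- frc$frc + cum_rec
    if (aerated <= 0) {
      stop("non-positive aerated lung volume", call. = FALSE)
    }
    if (p == 0) {
      eelv_p <- frc$frc
      vt <- mechanics$tidal_volume[nrow(mechanics)]
      step_valid <- TRUE
    } else {
      i <- match(p, mechanics$set_peep)
      eelv_p <- mechanics$eelv[i]
      vt <- mechanics$tidal_volume[i]
      step_valid <- mechanics$valid[i]
    }
    inflation <- eelv_p - aerated
    dynamic <- vt / aerated
    static <- inflation / aerated
    tibble::tibble(
      peep = p,
      aerated_volume = aerated,
      cumulative_recruitment = cum_rec,
      cumulative_inflation = inflation,
      dynamic_strain = dynamic,
      static_strain = static,
      total_strain = dynamic + static,
      valid = step_valid && all(below$valid)
    )
  })
  dplyr::bind_rows(rows)
}
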