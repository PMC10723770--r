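#' Analysis configuration
#'
#' Constants of the end-to-end analysis, defaulting to the study protocol:
#' EELV noise 25 ml per wash draw for uncertainty propagation, goodness-of-fit
#' alpha 0.05, implausibility bound 20, the 5-to-0 derecruitment range
#' included in the granular set and the fit.
#'
#' @param eelv_noise_sd EELV measurement SD per wash draw (ml) used to
#'   propagate per-point R/I uncertainty; 0 switches the fit to equal
#'   weights.
#' @param gof_alpha Goodness-of-fit significance level, in (0, 1).
#' @param implausibility_bound Implausibility threshold (> 0) on the vertex
#'   and predicted |R/I|.
#' @param include_zeep_step Include the 5-to-0 range (default TRUE).
#' @param extrapolation_max Upper PEEP bound for predictions (cm H2O).
#' @param weight_mode `"covariance"` (GLS with the propagated EELV-noise
#'   covariance, the calibrated default) or `"diagonal"` (per-point sigma
#'   only).
#' @param seed Optional integer seed recorded in run logs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(eelv_noise_sd = 25, gof_alpha = 0.05,
                       implausibility_bound = 20, include_zeep_step = TRUE,
                       extrapolation_max = 20,
                       weight_mode = c("covariance", "diagonal"),
                       seed = NULL) {
  weight_mode <- match.arg(weight_mode)
  if (!(gof_alpha > 0 && gof_alpha < 1)) {
    stop("gof_alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!(implausibility_bound > 0)) {
    stop("implausibility_bound must be > 0", call. = FALSE)
  }
  if (eelv_noise_sd < 0) stop("eelv_noise_sd must be >= 0", call. = FALSE)
  structure(
    list(eelv_noise_sd = eelv_noise_sd, gof_alpha = gof_alpha,
         implausibility_bound = implausibility_bound,
         include_zeep_step = include_zeep_step,
         extrapolation_max = extrapolation_max,
         weight_mode = weight_mode, seed = seed),
    class = "run_config"
  )
}

#' Analyze one patient trial
#'
#' Runs the full per-patient chain: eligibility screening, step mechanics,
#' FRC from the derecruitment breath, granular and global recruitment
#' decomposition, the strain profile, and the origin-constrained quadratic
#' R/I fit with its usability gate. Ranges invalidated by a failed EELV wash
#' pair are excluded from the fit; the fit is skipped (with a reason) when
#' fewer than 3 valid points remain.
#'
#' @param trial A [patient_trial()].
#' @param config A [run_config()].
#' @return A list of class `recrin_patient` with elements `trial`,
#'   `screening`, `mechanics`, `frc`, `ranges`, `global`, `strain`, `fit`,
#'   `gate`, `flags` (character log of substitutions and warnings).
#' @export
analyze_trial <- function(trial, config = run_config()) {
  stopifnot(inherits(trial, "patient_trial"), inherits(config, "run_config"))
  flags <- character()
  screening <- screen_trial(trial)
  mechanics <- trial_mechanics(trial)
  if (any(!mechanics$valid)) {
    flags <- c(flags, sprintf(
      "EELV pair failed the 20%% rule at PEEP %s",
      paste(mechanics$set_peep[!mechanics$valid], collapse = ", ")))
  }
  frc <- NULL
  if (!is.null(trial$derecruitment)) {
    frc <- compute_frc(mechanics$eelv[nrow(mechanics)], trial$derecruitment)
    if (frc$flagged) flags <- c(flags, "zero single-breath release volume")
  } else {
    flags <- c(flags, "no derecruitment breath: FRC and strain unavailable")
  }
  include_zeep <- config$include_zeep_step && !is.null(frc)
  ranges <- compute_granular_recruitment(trial, mechanics, frc,
                                         include_zeep = include_zeep)
  if (any(ranges$crs_substituted)) {
    flags <- c(flags, "5->0 range uses Crs at PEEP 5 (crs_substituted)")
  }
  if (any(ranges$negative_recruitment)) {
    flags <- c(flags, "negative recruited volume retained and flagged")
  }
  global <- compute_global_recruitment(mechanics)
  strain <- if (!is.null(frc)) {
    compute_strain_profile(trial, ranges, frc, mechanics)
  }

  fit <- NULL
  gate <- list(usable = FALSE, reason = "NO_FIT")
  pts <- ranges[ranges$valid, ]
  if (nrow(pts) >= 3 && length(unique(pts$mid_peep)) >= 2) {
    if (config$eelv_noise_sd > 0) {
      points <- data.frame(mid_peep = pts$mid_peep, ri_ratio = pts$ri_ratio,
                           sigma = ri_point_sigma(pts, config$eelv_noise_sd))
      covariance <- if (config$weight_mode == "covariance") {
        ri_point_covariance(pts, config$eelv_noise_sd)
      }
    } else {
      points <- data.frame(mid_peep = pts$mid_peep, ri_ratio = pts$ri_ratio,
                           sigma = 1)
      covariance <- NULL
    }
    fit <- fit_ri_curve(points, covariance = covariance,
                        gof_alpha = config$gof_alpha,
                        implausibility_bound = config$implausibility_bound,
                        extrapolation_max = config$extrapolation_max)
    gate <- gof_gate(fit)
  } else {
    flags <- c(flags, "fewer than 3 valid ranges: R/I curve not fitted")
  }

  structure(
    list(trial = trial, screening = screening, mechanics = mechanics,
         frc = frc, ranges = ranges, global = global, strain = strain,
         fit = fit, gate = gate, flags = flags),
    class = "recrin_patient"
  )
}

#' @export
print.recrin_patient <- function(x, ...) {
  cat(sprintf("<recrin_patient> %s: global R/I %.2f; %s\n",
              x$trial$patient_id, x$global$ri_ratio,
              if (is.null(x$fit)) "no fit" else
                sprintf("fit %s (gate: %s)", x$fit$shape,
                        if (x$gate$usable) "usable" else x$gate$reason)))
  invisible(x)
}

#' Analyze a cohort of trials
#'
#' Screens every trial, analyzes the eligible ones with [analyze_trial()],
#' and assembles tidy cohort tables: per-range recruitment, per-level strain,
#' fit summaries, per-patient intraindividual variability of the narrow-range
#' R/I and Crec, descriptive summaries (median and IQR) and the correlation
#' endpoints of [endpoint_table()].
#'
#' @param trials A list of [patient_trial()] objects, or of
#'   `list(trial, truth)` pairs as returned by [generate_cohort()].
#' @param config A [run_config()].
#' @return A list of class `recrin_cohort`: `patients` (per-patient
#'   analyses), `excluded` (screening failures), `tables` (tibbles:
#'   `screening`, `ranges`, `strain`, `fits`, `variability`, `summary`,
#'   `endpoints`).
#' @export
analyze_cohort <- function(trials, config = run_config()) {
  trials <- lapply(trials, function(x) {
    if (inherits(x, "patient_trial")) x else x$trial
  })
  screening_rows <- list()
  patients <- list()
  excluded <- list()
  for (tr in trials) {
    sc <- screen_trial(tr)
    screening_rows[[tr$patient_id]] <- tibble::tibble(
      patient_id = tr$patient_id, eligible = sc$eligible,
      reasons = paste(sc$reasons, collapse = ","),
      airway_opening_pressure = sc$airway_opening_pressure,
      skipped = paste(sc$skipped, collapse = ","))
    if (sc$eligible) {
      patients[[tr$patient_id]] <- analyze_trial(tr, config)
    } else {
      excluded[[tr$patient_id]] <- sc
    }
  }

  out <- structure(list(patients = patients, excluded = excluded,
                        config = config, tables = list()),
                   class = "recrin_cohort")
  out$tables$screening <- dplyr::bind_rows(screening_rows)

  if (length(patients) > 0) {
    add_id <- function(getter) {
      dplyr::bind_rows(lapply(patients, function(p) {
        tb <- getter(p)
        if (is.null(tb)) return(NULL)
        dplyr::bind_cols(tibble::tibble(patient_id = p$trial$patient_id), tb)
      }))
    }
    out$tables$ranges <- add_id(function(p) p$ranges)
    out$tables$strain <- add_id(function(p) p$strain)
    out$tables$fits <- dplyr::bind_rows(lapply(patients, function(p) {
      if (is.null(p$fit)) {
        return(tibble::tibble(patient_id = p$trial$patient_id,
                              b1 = NA_real_, b2 = NA_real_,
                              r_squared = NA_real_, chi_square = NA_real_,
                              gof_p = NA_real_, vertex_peep = NA_real_,
                              shape = NA_character_, implausible = NA,
                              usable = FALSE, reason = p$gate$reason))
      }
      tibble::tibble(patient_id = p$trial$patient_id,
                     b1 = p$fit$b1, b2 = p$fit$b2,
                     r_squared = p$fit$r_squared,
                     chi_square = p$fit$chi_square, gof_p = p$fit$gof_p,
                     vertex_peep = p$fit$vertex_peep, shape = p$fit$shape,
                     implausible = p$fit$implausible,
                     usable = p$gate$usable, reason = p$gate$reason)
    }))
    out$tables$variability <- dplyr::bind_rows(lapply(patients, function(p) {
      narrow <- p$ranges[!p$ranges$crs_substituted, ]
      cov_of <- function(v) {
        tryCatch(coefficient_of_variability(v)$cov_percent,
                 error = function(e) NA_real_)
      }
      tibble::tibble(patient_id = p$trial$patient_id,
                     n_ranges = nrow(narrow),
                     cov_ri_percent = cov_of(narrow$ri_ratio),
                     cov_crec_percent = cov_of(narrow$crec))
    }))

    glob <- function(field) {
      vapply(patients, function(p) p$global[[field]], numeric(1))
    }
    frcs <- vapply(patients, function(p) {
      if (is.null(p$frc)) NA_real_ else p$frc$frc
    }, numeric(1))
    mean_narrow <- function(field) {
      vapply(patients, function(p) {
        mean(p$ranges[[field]][!p$ranges$crs_substituted])
      }, numeric(1))
    }
    summary_of <- function(v, name) {
      tryCatch(cohort_summary(v, name), error = function(e) NULL)
    }
    out$tables$summary <- dplyr::bind_rows(
      summary_of(frcs, "frc_ml"),
      summary_of(glob("v_rec"), "global_v_rec_ml"),
      summary_of(glob("crec"), "global_crec_ml_per_cmh2o"),
      summary_of(glob("ri_ratio"), "global_ri_ratio"),
      summary_of(mean_narrow("ri_ratio"), "mean_granular_ri_ratio"),
      summary_of(mean_narrow("crec"), "mean_granular_crec_ml_per_cmh2o"),
      summary_of(out$tables$variability$cov_ri_percent,
                 "cov_granular_ri_percent"),
      summary_of(out$tables$variability$cov_crec_percent,
                 "cov_granular_crec_percent")
    )
    out$tables$endpoints <- if (length(patients) >= 3 &&
                                  !is.null(out$tables$strain) &&
                                  nrow(out$tables$strain) > 0) {
      endpoint_table(out)
    }
  }
  out
}

#' @export
print.recrin_cohort <- function(x, ...) {
  cat(sprintf("<recrin_cohort> %d analyzed, %d excluded by screening\n",
              length(x$patients), length(x$excluded)))
  if (!is.null(x$tables$summary)) {
    s <- x$tables$summary
    ri <- s[s$variable == "global_ri_ratio", ]
    if (nrow(ri) == 1) {
      cat(sprintf("  global R/I median %.2f [%.2f to %.2f] (n = %d)\n",
                  ri$median, ri$iqr_low, ri$iqr_high, ri$n))
    }
  }
  invisible(x)
}
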