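#' Parameters of a synthetic patient
#'
#' Ground truth for a virtual decremental-PEEP-trial patient. Recruitability
#' is parameterized directly on the origin-constrained quadratic law
#' `RI(P) = b1*P + b2*P^2`; the compliance of the recruited lung follows as
#' `Crec(P) = crs_baby * RI(P)`, so the true EELV has the closed form
#' `EELV(p) = frc_true + crs_baby * (p + b1*p^2/2 + b2*p^3/3)`.
#'
#' `crs_mode` selects the measured-compliance profile emitted through the
#' plateau pressures: `"constant"` (default) keeps the measured Crs equal to
#' the baby-lung compliance at every step, which is the profile under which
#' the measured granular R/I reproduces the generating law (up to the exact
#' quadrature term, see [ground_truth()]); `"recruited"` makes recruited
#' tissue add tidal compliance (`Crs(p) = crs_baby * (1 + RI(p))`), a
#' deliberately discordant profile that exercises the non-additivity of
#' granular versus global recruited volumes.
#'
#' @param frc_true True functional residual capacity (ml).
#' @param crs_baby Baby-lung compliance (ml/cm H2O), constant over PEEP.
#' @param b1_true,b2_true Coefficients of the true R/I law (per cm H2O and
#'   per cm H2O squared). `RI(P)` must stay above -0.5 over the tested range
#'   (physiological sanity bound).
#' @param tidal_volume Tidal volume (ml).
#' @param eelv_noise_sd EELV measurement noise per wash draw (ml), >= 0.
#' @param peep_levels Decremental ladder (cm H2O), default
#'   `c(15, 13, 10, 8, 5)`.
#' @param include_zeep_breath Emit the 5-to-0 derecruitment breath.
#' @param intrinsic_peep Intrinsic PEEP (cm H2O) added to the total PEEP and
#'   recorded on the trial; default 0.
#' @param aop_true True airway opening pressure (cm H2O) shaping the
#'   low-flow curve; 0 means no airway closure.
#' @param crs_mode Measured-compliance profile, `"constant"` or
#'   `"recruited"`.
#' @param seed Integer seed; the same seed reproduces the trial exactly.
#' @param patient_id Identifier for the emitted trial.
#' @return An object of class `synthetic_patient_params`.
#' @export
synthetic_patient_params <- function(frc_true = 1343, crs_baby = 40,
                                     b1_true = 0.3, b2_true = -0.01,
                                     tidal_volume = 420, eelv_noise_sd = 25,
                                     peep_levels = c(15, 13, 10, 8, 5),
                                     include_zeep_breath = TRUE,
                                     intrinsic_peep = 0, aop_true = 0,
                                     crs_mode = c("constant", "recruited"),
                                     seed = 1L, patient_id = "SYN001") {
  crs_mode <- match.arg(crs_mode)
  stopifnot(frc_true > 0, crs_baby > 0, tidal_volume > 0,
            eelv_noise_sd >= 0, length(peep_levels) >= 2)
  peep_levels <- sort(as.numeric(peep_levels), decreasing = TRUE)
  if (anyDuplicated(peep_levels)) {
    stop("peep_levels must be distinct", call. = FALSE)
  }
  grid <- seq(0, max(peep_levels), length.out = 201)
  if (min(b1_true * grid + b2_true * grid^2) < -0.5) {
    stop("R/I law dips below -0.5 over the tested PEEP range: implausible",
         call. = FALSE)
  }
  structure(
    list(frc_true = frc_true, crs_baby = crs_baby,
         b1_true = b1_true, b2_true = b2_true,
         tidal_volume = tidal_volume, eelv_noise_sd = eelv_noise_sd,
         peep_levels = peep_levels,
         include_zeep_breath = include_zeep_breath,
         intrinsic_peep = intrinsic_peep, aop_true = aop_true,
         crs_mode = crs_mode, seed = as.integer(seed),
         patient_id = patient_id),
    class = "synthetic_patient_params"
  )
}

ri_law <- function(params, p) {
  params$b1_true * p + params$b2_true * p^2
}

eelv_law <- function(params, p) {
  params$frc_true + params$crs_baby *
    (p + params$b1_true * p^2 / 2 + params$b2_true * p^3 / 3)
}

measured_crs <- function(params, p) {
  switch(params$crs_mode,
         constant = rep(params$crs_baby, length(p)),
         recruited = params$crs_baby * (1 + ri_law(params, p)))
}

#' Analytic ground truth for a synthetic patient
#'
#' Regenerates, from the parameters alone, the quantities the pipeline is
#' expected to recover: the true recruited volume of every derecruitment
#' range (the integral of `Crec(P) = crs_baby * RI(P)` over the range), the
#' range-averaged R/I ratio — which equals `RI(mid_peep) + b2 * delta^2 / 12`
#' exactly, the integral mean of a quadratic over the range — and the true
#' strain profile. Under `crs_mode = "constant"` and zero noise these are
#' exactly what the pipeline computes; under `"recruited"` the measured
#' low-PEEP compliance absorbs part of the EELV change and the pipeline's
#' granular R/I deliberately differs.
#'
#' @param params A [synthetic_patient_params()].
#' @return A list with `params`, `ranges` (tibble: `peep_high`, `peep_low`,
#'   `mid_peep`, `delta_peep`, `v_rec_true`, `ri_true`), `strain` (tibble per
#'   PEEP level: `aerated_volume`, `dynamic_strain`, `static_strain`,
#'   `total_strain`) and `eelv_true` at the trial levels.
#' @export
ground_truth <- function(params) {
  stopifnot(inherits(params, "synthetic_patient_params"))
  peeps <- params$peep_levels
  hi <- peeps[-length(peeps)]
  lo <- peeps[-1]
  if (params$include_zeep_breath) {
    hi <- c(hi, min(peeps))
    lo <- c(lo, 0)
  }
  crec_integral <- function(a, b) {
    params$crs_baby * (params$b1_true * (a^2 - b^2) / 2 +
                         params$b2_true * (a^3 - b^3) / 3)
  }
  delta <- hi - lo
  mid <- (hi + lo) / 2
  ranges <- tibble::tibble(
    peep_high = hi, peep_low = lo, mid_peep = mid, delta_peep = delta,
    v_rec_true = crec_integral(hi, lo),
    ri_true = ri_law(params, mid) + params$b2_true * delta^2 / 12
  )
  levels <- sort(unique(c(0, peeps)))
  aerated <- params$frc_true + params$crs_baby *
    (params$b1_true * levels^2 / 2 + params$b2_true * levels^3 / 3)
  dynamic <- params$tidal_volume / aerated
  static <- params$crs_baby * levels / aerated
  strain <- tibble::tibble(
    peep = levels, aerated_volume = aerated,
    dynamic_strain = dynamic, static_strain = static,
    total_strain = dynamic + static
  )
  list(params = params, ranges = ranges, strain = strain,
       eelv_true = stats::setNames(eelv_law(params, peeps),
                                   as.character(peeps)))
}

#' Generate one synthetic patient trial
#'
#' Emits a [patient_trial()] following the study protocol: EELV wash-out and
#' wash-in at each ladder step are two independent Gaussian draws around the
#' true EELV; plateau pressures are back-computed from the target measured
#' compliance profile and reported at 0.1 cm H2O resolution (ventilator
#' display); the derecruitment breath releases the true PEEP-5 volume plus
#' one noise draw; a low-flow inflation curve reflects `aop_true`. The same
#' seed reproduces the trial bit-for-bit.
#'
#' @param params A [synthetic_patient_params()].
#' @return A list with `trial` (a [patient_trial()]) and `truth` (see
#'   [ground_truth()]).
#' @export
#' @examples
#' gp <- generate_patient(synthetic_patient_params(eelv_noise_sd = 0))
#' gp$trial
generate_patient <- function(params) {
  stopifnot(inherits(params, "synthetic_patient_params"))
  truth <- ground_truth(params)
  peeps <- params$peep_levels
  withr::with_seed(params$seed, {
    draw_pair <- function(mu) {
      for (attempt in 1:100) {
        pair <- stats::rnorm(2, mu, params$eelv_noise_sd)
        if (all(pair > 0)) return(pair)
        warning("non-positive EELV draw; resampling", call. = FALSE)
      }
      stop("failed to draw a positive EELV in 100 attempts", call. = FALSE)
    }
    washes <- lapply(eelv_law(params, peeps), draw_pair)
    crs_target <- measured_crs(params, peeps)
    total_peep <- peeps + params$intrinsic_peep
    plateau <- round(total_peep + params$tidal_volume / crs_target, 1)
    steps <- tibble::tibble(
      set_peep = peeps,
      total_peep = total_peep,
      plateau_pressure = plateau,
      tidal_volume = params$tidal_volume,
      eelv_washout = vapply(washes, `[`, numeric(1), 1),
      eelv_washin = vapply(washes, `[`, numeric(1), 2)
    )
    dere <- NULL
    if (params$include_zeep_breath) {
      p_low <- min(peeps)
      released <- (eelv_law(params, p_low) - params$frc_true) +
        stats::rnorm(1, 0, params$eelv_noise_sd)
      dere <- derecruitment_breath(
        inspired_vt = params$tidal_volume,
        exhaled_vt = params$tidal_volume + released,
        from_peep = p_low, to_peep = 0
      )
    }
    pressures <- 0:20
    volumes <- params$crs_baby * pmax(pressures - params$aop_true, 0)
    trial <- patient_trial(
      patient_id = params$patient_id,
      steps = steps,
      derecruitment = dere,
      low_flow = low_flow_curve(pressures, volumes),
      intrinsic_peep = params$intrinsic_peep
    )
    list(trial = trial, truth = truth)
  })
}

#' Archetype parameter ranges
#'
#' Per-archetype uniform sampling ranges for the R/I law used by
#' [generate_cohort()]. Values are chosen to span the recruitability
#' phenotypes seen clinically: strong recruiters (global R/I well above 1),
#' weak recruiters (below 0.5), clearly parabolic saturating responders
#' (vertex inside the tested ladder), linear ever-increasing responders, and
#' non-recruiters (flat zero law).
#'
#' @return A data frame with one row per archetype: `b1_min`, `b1_max`,
#'   `b2_min`, `b2_max`.
#' @export
archetype_ranges <- function() {
  data.frame(
    archetype = c("high_recruiter", "low_recruiter", "parabolic_saturating",
                  "linear_increasing", "non_recruiter"),
    b1_min = c(0.20, 0.04, 0.24, 0.04, 0),
    b1_max = c(0.32, 0.10, 0.36, 0.12, 0),
    b2_min = c(-0.011, -0.004, -0.016, 0, 0),
    b2_max = c(-0.006, -0.001, -0.010, 0, 0)
  )
}

#' Generate a synthetic cohort
#'
#' Draws `n` virtual patients whose R/I-law coefficients come from the
#' archetype mix, with functional residual capacity, baby-lung compliance and
#' predicted body weight sampled from realistic clinical ranges
#' (FRC 900-1750 ml, compliance 28-52 ml/cm H2O, weight 55-85 kg with a
#' 6 ml/kg tidal volume). Deterministic under `seed`.
#'
#' @param n Number of patients (>= 0).
#' @param archetype_mix Named fractions over the archetypes of
#'   [archetype_ranges()], summing to 1.
#' @param seed Integer seed.
#' @param eelv_noise_sd EELV noise per wash draw (ml), default 25.
#' @param crs_mode Measured-compliance profile passed to every patient.
#' @param intrinsic_peep,aop_true Pathology parameters applied to every
#'   patient (defaults 0: screen-clean cohort).
#' @return A list of `list(trial, truth)` pairs (see [generate_patient()]).
#' @export
#' @examples
#' cohort <- generate_cohort(3, c(high_recruiter = 1), seed = 7)
#' length(cohort)
generate_cohort <- function(n,
                            archetype_mix = c(high_recruiter = 0.30,
                                              low_recruiter = 0.25,
                                              parabolic_saturating = 0.25,
                                              linear_increasing = 0.10,
                                              non_recruiter = 0.10),
                            seed = 1L, eelv_noise_sd = 25,
                            crs_mode = "constant",
                            intrinsic_peep = 0, aop_true = 0) {
  known <- archetype_ranges()
  bad <- setdiff(names(archetype_mix), known$archetype)
  if (length(bad) > 0) {
    stop(sprintf("unknown archetype(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (abs(sum(archetype_mix) - 1) > 1e-8) {
    stop("archetype_mix fractions must sum to 1", call. = FALSE)
  }
  if (n == 0) return(list())
  withr::with_seed(seed, {
    arche <- sample(names(archetype_mix), n, replace = TRUE,
                    prob = archetype_mix)
    frc <- stats::runif(n, 900, 1750)
    crs <- stats::runif(n, 28, 52)
    pbw <- stats::runif(n, 55, 85)
    u1 <- stats::runif(n)
    u2 <- stats::runif(n)
    seeds <- sample.int(.Machine$integer.max - 1, n)
    lapply(seq_len(n), function(i) {
      rg <- known[known$archetype == arche[i], ]
      params <- synthetic_patient_params(
        frc_true = frc[i], crs_baby = crs[i],
        b1_true = rg$b1_min + u1[i] * (rg$b1_max - rg$b1_min),
        b2_true = rg$b2_min + u2[i] * (rg$b2_max - rg$b2_min),
        tidal_volume = 6 * pbw[i], eelv_noise_sd = eelv_noise_sd,
        crs_mode = crs_mode,
        intrinsic_peep = intrinsic_peep, aop_true = aop_true,
        seed = seeds[i], patient_id = sprintf("SYN%03d", i)
      )
      out <- generate_patient(params)
      out$archetype <- arche[i]
      out
    })
  })
}
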