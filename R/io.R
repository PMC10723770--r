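#' Read patient trials from disk
#'
#' Reads the trial files written by [write_trials()]. The CSV layout is one
#' row per (patient, step) in `<path>`, a per-patient metadata table in
#' `<stem>_meta.csv` (derecruitment breath, intrinsic PEEP, predicted body
#' weight) and, when present, low-flow curves in `<stem>_lowflow.csv`. The
#' JSON layout is one nested object per patient in a single file.
#'
#' @param path Path to the steps CSV or the JSON file.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return A list of [patient_trial()] objects, steps sorted by descending
#'   set PEEP.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "json") read_trials_json(path) else read_trials_csv(path)
}

#' Write patient trials to disk
#'
#' Inverse of [read_trials()]: `read_trials(write_trials(x, p), p)` returns
#' the same trials field-for-field (numbers round-trip at full double
#' precision in JSON and at 15 significant digits in CSV).
#'
#' @param trials List of [patient_trial()] objects (may be empty).
#' @param path Output path for the steps CSV or the JSON file.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return Invisibly, the paths written.
#' @export
write_trials <- function(trials, path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  stopifnot(is.list(trials))
  for (tr in trials) {
    if (!inherits(tr, "patient_trial")) {
      stop("write_trials expects a list of patient_trial objects",
           call. = FALSE)
    }
  }
  if (format == "json") write_trials_json(trials, path)
  else write_trials_csv(trials, path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") "json" else "csv"
}

sidecar_paths <- function(path) {
  stem <- tools::file_path_sans_ext(path)
  list(meta = paste0(stem, "_meta.csv"),
       lowflow = paste0(stem, "_lowflow.csv"))
}

trial_to_list <- function(tr) {
  out <- list(
    patient_id = tr$patient_id,
    steps = as.data.frame(tr$steps)
  )
  if (!is.null(tr$predicted_body_weight)) {
    out$predicted_body_weight <- tr$predicted_body_weight
  }
  if (!is.null(tr$intrinsic_peep)) out$intrinsic_peep <- tr$intrinsic_peep
  if (!is.null(tr$derecruitment)) {
    out$derecruitment <- unclass(tr$derecruitment)
  }
  if (!is.null(tr$low_flow)) {
    out$low_flow <- as.data.frame(tr$low_flow)
  }
  out
}

list_to_trial <- function(x) {
  patient_trial(
    patient_id = x$patient_id,
    steps = as.data.frame(x$steps),
    derecruitment = if (!is.null(x$derecruitment)) {
      do.call(derecruitment_breath, as.list(x$derecruitment))
    },
    low_flow = if (!is.null(x$low_flow)) {
      low_flow_curve(x$low_flow$pressure, x$low_flow$volume)
    },
    intrinsic_peep = x$intrinsic_peep,
    predicted_body_weight = x$predicted_body_weight
  )
}

write_trials_json <- function(trials, path) {
  jsonlite::write_json(lapply(trials, trial_to_list), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

read_trials_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows_to_df <- function(rows) {
    do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  }
  lapply(raw, function(x) {
    x$steps <- rows_to_df(x$steps)
    if (!is.null(x$low_flow)) x$low_flow <- rows_to_df(x$low_flow)
    list_to_trial(x)
  })
}

write_trials_csv <- function(trials, path) {
  side <- sidecar_paths(path)
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.15g", col) else col
    })
    df
  }
  steps <- do.call(rbind, c(
    list(data.frame(patient_id = character(),
                    stats::setNames(
                      replicate(length(step_columns), numeric(),
                                simplify = FALSE), step_columns))),
    lapply(trials, function(tr) {
      cbind(data.frame(patient_id = tr$patient_id), as.data.frame(tr$steps))
    })))
  utils::write.csv(fmt(steps), path, row.names = FALSE, quote = FALSE)

  meta <- do.call(rbind, c(
    list(data.frame(patient_id = character(),
                    predicted_body_weight = numeric(),
                    intrinsic_peep = numeric(),
                    dere_inspired_vt = numeric(), dere_exhaled_vt = numeric(),
                    dere_from_peep = numeric(), dere_to_peep = numeric())),
    lapply(trials, function(tr) {
      data.frame(
        patient_id = tr$patient_id,
        predicted_body_weight = tr$predicted_body_weight %||% NA_real_,
        intrinsic_peep = tr$intrinsic_peep %||% NA_real_,
        dere_inspired_vt = tr$derecruitment$inspired_vt %||% NA_real_,
        dere_exhaled_vt = tr$derecruitment$exhaled_vt %||% NA_real_,
        dere_from_peep = tr$derecruitment$from_peep %||% NA_real_,
        dere_to_peep = tr$derecruitment$to_peep %||% NA_real_
      )
    })))
  utils::write.csv(fmt(meta), side$meta, row.names = FALSE, quote = FALSE)

  lf <- do.call(rbind, c(
    list(data.frame(patient_id = character(), pressure = numeric(),
                    volume = numeric())),
    lapply(trials, function(tr) {
      if (is.null(tr$low_flow)) return(NULL)
      cbind(data.frame(patient_id = tr$patient_id),
            as.data.frame(tr$low_flow))
    })))
  if (nrow(lf) > 0) {
    utils::write.csv(fmt(lf), side$lowflow, row.names = FALSE, quote = FALSE)
  } else if (file.exists(side$lowflow)) {
    unlink(side$lowflow)
  }
  invisible(c(path, side$meta,
              if (nrow(lf) > 0) side$lowflow))
}

read_trials_csv <- function(path) {
  side <- sidecar_paths(path)
  steps <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", step_columns)
  missing_cols <- setdiff(need, names(steps))
  if (length(missing_cols) > 0) {
    stop(sprintf("trials CSV is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  meta <- if (file.exists(side$meta)) {
    utils::read.csv(side$meta, stringsAsFactors = FALSE)
  } else NULL
  lf <- if (file.exists(side$lowflow)) {
    utils::read.csv(side$lowflow, stringsAsFactors = FALSE)
  } else NULL
  ids <- unique(steps$patient_id)
  lapply(ids, function(id) {
    m <- if (!is.null(meta) && id %in% meta$patient_id) {
      meta[match(id, meta$patient_id), ]
    } else NULL
    curve <- if (!is.null(lf) && id %in% lf$patient_id) {
      sub <- lf[lf$patient_id == id, ]
      low_flow_curve(sub$pressure, sub$volume)
    } else NULL
    dere <- NULL
    if (!is.null(m) && is.finite(m$dere_inspired_vt)) {
      dere <- derecruitment_breath(m$dere_inspired_vt, m$dere_exhaled_vt,
                                   m$dere_from_peep, m$dere_to_peep)
    }
    patient_trial(
      patient_id = id,
      steps = steps[steps$patient_id == id, step_columns],
      derecruitment = dere,
      low_flow = curve,
      intrinsic_peep = if (!is.null(m) && is.finite(m$intrinsic_peep)) {
        m$intrinsic_peep
      },
      predicted_body_weight = if (!is.null(m) &&
                                    is.finite(m$predicted_body_weight)) {
        m$predicted_body_weight
      }
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
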