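# Fixtures built in code: small deterministic trials used across test files.

make_steps <- function(peeps = c(15, 13, 10, 8, 5), crs = 40, vt = 420,
                       eelv = function(p) 1300 + 45 * p) {
  do.call(rbind, lapply(peeps, function(p) {
    peep_step(p, p, p + vt / crs, vt, eelv(p), eelv(p))
  }))
}

make_trial <- function(patient_id = "T001", peeps = c(15, 13, 10, 8, 5),
                       crs = 40, vt = 420,
                       eelv = function(p) 1300 + 45 * p,
                       with_breath = TRUE, ...) {
  breath <- if (with_breath) {
    derecruitment_breath(vt, vt + (eelv(5) - 1300), from_peep = 5)
  }
  patient_trial(patient_id, make_steps(peeps, crs, vt, eelv),
                derecruitment = breath, ...)
}

# straight-line low-flow curve (no closure) and a closed-airway curve
open_curve <- function(slope = 30) low_flow_curve(0:15, slope * (0:15))
closed_curve <- function(aop = 8, slope = 30) {
  low_flow_curve(0:20, slope * pmax(0:20 - aop, 0))
}

expect_trial_equal <- function(a, b, tolerance = 1e-9) {
  expect_equal(a$patient_id, b$patient_id)
  expect_equal(as.data.frame(a$steps), as.data.frame(b$steps),
               tolerance = tolerance)
  expect_equal(is.null(a$derecruitment), is.null(b$derecruitment))
  if (!is.null(a$derecruitment)) {
    expect_equal(unclass(a$derecruitment), unclass(b$derecruitment),
                 tolerance = tolerance)
  }
  expect_equal(is.null(a$low_flow), is.null(b$low_flow))
  if (!is.null(a$low_flow)) {
    expect_equal(as.data.frame(a$low_flow), as.data.frame(b$low_flow),
                 tolerance = tolerance)
  }
  expect_equal(a$intrinsic_peep, b$intrinsic_peep, tolerance = tolerance)
  expect_equal(a$predicted_body_weight, b$predicted_body_weight,
               tolerance = tolerance)
}
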