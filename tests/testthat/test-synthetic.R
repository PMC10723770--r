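test_that("the same seed reproduces a trial bit-for-bit; seeds differ otherwise", {
  p <- synthetic_patient_params(seed = 42)
  a <- generate_patient(p)
  b <- generate_patient(p)
  expect_identical(a$trial$steps, b$trial$steps)
  expect_identical(a$trial$derecruitment, b$trial$derecruitment)
  c_ <- generate_patient(synthetic_patient_params(seed = 43))
  expect_false(isTRUE(all.equal(a$trial$steps$eelv_washout,
                                c_$trial$steps$eelv_washout)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_patient(synthetic_patient_params(seed = 7)))
  expect_identical(runif(1), before)
})

test_that("parameter invariants are enforced", {
  expect_error(synthetic_patient_params(frc_true = -1), "frc_true")
  expect_error(synthetic_patient_params(b1_true = 0, b2_true = -0.05),
               "implausible")
  expect_error(synthetic_patient_params(peep_levels = c(10, 10, 5)),
               "distinct")
})

test_that("noise-free trials reproduce the analytic ground truth", {
  p <- synthetic_patient_params(eelv_noise_sd = 0, seed = 2)
  gp <- generate_patient(p)
  truth <- gp$truth
  res <- analyze_trial(gp$trial, run_config(eelv_noise_sd = 0))
  expect_equal(res$frc$frc, p$frc_true, tolerance = 1e-12)
  expect_equal(res$ranges$v_rec, truth$ranges$v_rec_true, tolerance = 1e-9)
  expect_equal(res$ranges$ri_ratio, truth$ranges$ri_true, tolerance = 1e-9)
  st <- res$strain
  expect_equal(st$aerated_volume, truth$strain$aerated_volume,
               tolerance = 1e-9)
  expect_equal(st$dynamic_strain, truth$strain$dynamic_strain,
               tolerance = 1e-9)
  expect_equal(st$static_strain, truth$strain$static_strain,
               tolerance = 1e-9)
})

test_that("the discordant measured-compliance profile breaks additivity", {
  pc <- synthetic_patient_params(eelv_noise_sd = 0, crs_mode = "constant")
  pr <- synthetic_patient_params(eelv_noise_sd = 0, crs_mode = "recruited")
  for (mode in list(pc, pr)) {
    res <- analyze_trial(generate_patient(mode)$trial,
                         run_config(eelv_noise_sd = 0))
    gap <- abs(sum(res$ranges$v_rec[!res$ranges$crs_substituted]) -
                 res$global$v_rec)
    if (mode$crs_mode == "constant") expect_lt(gap, 1e-8)
    else expect_gt(gap, 1)
  }
})

test_that("estimation error grows with the EELV noise level", {
  sds <- c(10, 25, 50)
  rmse <- vapply(seq_along(sds), function(k) {
    errs <- vapply(1:120, function(i) {
      p <- synthetic_patient_params(eelv_noise_sd = sds[k],
                                    seed = 1000 * k + i)
      mech <- trial_mechanics(generate_patient(p)$trial)
      truth_global <- ri_law_value <- 0.3 * 10 - 0.01 * 100 - 0.01 * 100 / 12
      compute_global_recruitment(mech)$ri_ratio - truth_global
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("cohort generation honors archetypes, mix validation and seeds", {
  all_parab <- generate_cohort(12, c(parabolic_saturating = 1), seed = 6)
  for (x in all_parab) {
    expect_lt(x$truth$params$b2_true, 0)
    expect_equal(x$archetype, "parabolic_saturating")
  }
  expect_error(generate_cohort(5, c(high_recruiter = 0.5,
                                    non_recruiter = 0.4)),
               "sum to 1")
  expect_error(generate_cohort(5, c(super_recruiter = 1)), "unknown")
  expect_length(generate_cohort(0), 0)

  a <- generate_cohort(6, seed = 31)
  b <- generate_cohort(6, seed = 31)
  expect_identical(lapply(a, function(x) x$trial$steps),
                   lapply(b, function(x) x$trial$steps))
  d <- generate_cohort(6, seed = 32)
  expect_false(identical(a[[1]]$trial$steps$eelv_washout,
                         d[[1]]$trial$steps$eelv_washout))
})

test_that("pathology parameters shape the emitted screening inputs", {
  sick <- generate_patient(synthetic_patient_params(aop_true = 9, seed = 3))
  expect_equal(detect_airway_opening_pressure(sick$trial$low_flow), 9)
  ip <- generate_patient(synthetic_patient_params(intrinsic_peep = 3,
                                                  seed = 3))
  expect_equal(ip$trial$intrinsic_peep, 3)
  expect_equal(ip$trial$steps$total_peep, ip$trial$steps$set_peep + 3)
})
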