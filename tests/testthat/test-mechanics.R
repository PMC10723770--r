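test_that("driving pressure and compliance follow the stated formulas", {
  m <- compute_step_mechanics(peep_step(15, 15, 25, 420, 1500, 1500))
  expect_equal(m$driving_pressure, 10)
  expect_equal(m$crs, 42)

  m2 <- compute_step_mechanics(peep_step(5, 5, 29, 360, 1500, 1500))
  expect_equal(m2$driving_pressure, 24)
  expect_equal(m2$crs, 15)

  bad <- peep_step(15, 15, 25, 420, 1500, 1500)
  bad$plateau_pressure <- 15
  expect_error(compute_step_mechanics(bad), "plateau")
})

test_that("FRC is the PEEP-5 EELV minus the single-breath released volume", {
  r <- compute_frc(1500, derecruitment_breath(420, 520))
  expect_equal(r$peep5_volume, 100)
  expect_equal(r$frc, 1400)
  expect_false(r$flagged)

  z <- compute_frc(1500, derecruitment_breath(420, 420))
  expect_equal(z$frc, 1500)
  expect_true(z$flagged)

  expect_equal(compute_frc(1343, derecruitment_breath(420, 570))$frc, 1193)
  expect_error(compute_frc(1500, derecruitment_breath(520, 420)),
               "negative release")
  expect_warning(compute_frc(1500, derecruitment_breath(420, 520,
                                                        from_peep = 8)),
                 "protocol")
})

test_that("the range decomposition matches hand evaluation", {
  h <- tibble::tibble(set_peep = 15, crs = 35, eelv = 2400, valid = TRUE)
  l <- tibble::tibble(set_peep = 5, crs = 30, eelv = 1900, valid = TRUE)
  r <- compute_range_recruitment(h, l)
  expect_equal(r$peep_vol, 500)
  expect_equal(r$inflation_vol, 300)
  expect_equal(r$v_rec, 200)
  expect_equal(r$crec, 20)
  expect_equal(r$ri_ratio, 200 / 300)
  expect_equal(r$mid_peep, 10)

  h2 <- tibble::tibble(set_peep = 13, crs = 42, eelv = 2150, valid = TRUE)
  l2 <- tibble::tibble(set_peep = 10, crs = 40, eelv = 1900, valid = TRUE)
  r2 <- compute_range_recruitment(h2, l2)
  expect_equal(r2$peep_vol, 250)
  expect_equal(r2$inflation_vol, 120)
  expect_equal(r2$v_rec, 130)
  expect_equal(r2$crec, 130 / 3)
  expect_equal(r2$ri_ratio, 130 / 120)

  # EELV change exactly equal to predicted inflation: zero recruitment
  l3 <- tibble::tibble(set_peep = 5, crs = 30, eelv = 2100, valid = TRUE)
  r3 <- compute_range_recruitment(h, l3)
  expect_equal(r3$v_rec, 0)
  expect_equal(r3$ri_ratio, 0)

  expect_error(compute_range_recruitment(l, l), "exceed")
})

test_that("negative recruited volume is retained and flagged, not clipped", {
  h <- tibble::tibble(set_peep = 15, crs = 35, eelv = 2100, valid = TRUE)
  l <- tibble::tibble(set_peep = 5, crs = 30, eelv = 1900, valid = TRUE)
  r <- compute_range_recruitment(h, l)
  expect_equal(r$v_rec, -100)
  expect_true(r$negative_recruitment)
  expect_lt(r$ri_ratio, 0)
})

test_that("granular ranges cover the ladder plus the 5-to-0 step", {
  tr <- make_trial()
  ranges <- compute_granular_recruitment(tr)
  expect_equal(nrow(ranges), 5)
  expect_equal(ranges$mid_peep, c(14, 11.5, 9, 6.5, 2.5))
  expect_equal(ranges$crs_substituted, c(rep(FALSE, 4), TRUE))
  # substituted compliance equals the PEEP-5 Crs
  mech <- trial_mechanics(tr)
  expect_equal(ranges$crs_low[5], mech$crs[5])
  # without the breath the zeep range is absent
  expect_equal(nrow(compute_granular_recruitment(
    make_trial(with_breath = FALSE))), 4)
})

test_that("an invalid wash pair invalidates exactly the touching ranges", {
  tr <- make_trial()
  tr$steps$eelv_washout[3] <- tr$steps$eelv_washin[3] * 1.5  # PEEP 10
  ranges <- compute_granular_recruitment(tr)
  expect_equal(ranges$valid, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  strain <- compute_strain_profile(
    tr, ranges, compute_frc(trial_mechanics(tr)$eelv[5], tr$derecruitment))
  expect_false(strain$valid[strain$peep == 10])
  expect_true(strain$valid[strain$peep == 5])
})

test_that("the decomposition identity peep_vol = inflation + v_rec is exact", {
  set.seed(21)
  for (i in 1:30) {
    h <- tibble::tibble(set_peep = runif(1, 10, 16),
                        crs = runif(1, 15, 60),
                        eelv = runif(1, 1800, 3000), valid = TRUE)
    l <- tibble::tibble(set_peep = runif(1, 2, 9),
                        crs = runif(1, 15, 60),
                        eelv = runif(1, 1000, 1800), valid = TRUE)
    r <- compute_range_recruitment(h, l)
    expect_equal(r$peep_vol, r$inflation_vol + r$v_rec, tolerance = 1e-12)
    expect_equal(sign(r$ri_ratio), sign(r$v_rec))
  }
})

test_that("the strain chain reproduces hand-computed values", {
  tr <- make_trial()
  frc <- list(frc = 1400, peep5_volume = 200, flagged = FALSE)
  ranges <- tibble::tibble(
    peep_high = c(15, 5), peep_low = c(5, 0), v_rec = c(250, 100),
    crs_substituted = c(FALSE, TRUE), valid = TRUE)
  mech <- tibble::tibble(set_peep = c(15, 5), eelv = c(2300, 1600),
                         tidal_volume = 420, valid = TRUE)
  st <- compute_strain_profile(tr, ranges, frc, mech)
  s5 <- st[st$peep == 5, ]
  expect_equal(s5$aerated_volume, 1500)
  expect_equal(s5$dynamic_strain, 0.28)
  expect_equal(s5$cumulative_inflation, 100)
  expect_equal(s5$static_strain, 100 / 1500)
  expect_equal(s5$total_strain, 0.28 + 100 / 1500)
  # zero PEEP: static strain identically 0, dynamic = VT / FRC
  s0 <- st[st$peep == 0, ]
  expect_identical(s0$static_strain, 0)
  expect_equal(s0$dynamic_strain, 420 / 1400)
  expect_equal(st$total_strain, st$dynamic_strain + st$static_strain)
})

test_that("a non-recruiting patient keeps dynamic strain constant across PEEP", {
  p <- synthetic_patient_params(b1_true = 0, b2_true = 0, eelv_noise_sd = 0)
  res <- analyze_trial(generate_patient(p)$trial,
                       run_config(eelv_noise_sd = 0))
  expect_equal(res$ranges$v_rec, rep(0, 5), tolerance = 1e-9)
  expect_equal(res$ranges$ri_ratio, rep(0, 5), tolerance = 1e-12)
  expect_equal(res$frc$frc, 1343)
  expect_equal(diff(res$strain$dynamic_strain), rep(0, 5), tolerance = 1e-12)
})
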