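ri_points <- function(b1, b2, mids = c(2.5, 6.5, 9, 11.5, 14), sigma = NULL) {
  out <- data.frame(mid_peep = mids, ri_ratio = b1 * mids + b2 * mids^2)
  if (!is.null(sigma)) out$sigma <- sigma
  out
}

test_that("noise-free quadratic data are recovered exactly", {
  fit <- fit_ri_curve(ri_points(0.3, -0.01))
  expect_equal(fit$b1, 0.3, tolerance = 1e-12)
  expect_equal(fit$b2, -0.01, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$vertex_peep, 15, tolerance = 1e-9)
  expect_equal(fit$shape, "saturating")
  expect_false(fit$implausible)
  expect_true(gof_gate(fit)$usable)
})

test_that("the linear degenerate case classifies as ever-increasing", {
  fit <- fit_ri_curve(ri_points(0.05, 0))
  expect_equal(fit$b1, 0.05, tolerance = 1e-12)
  expect_equal(fit$b2, 0, tolerance = 1e-12)
  expect_true(is.na(fit$vertex_peep))
  expect_equal(fit$shape, "ever_increasing")
})

test_that("degenerate designs are rejected", {
  expect_error(fit_ri_curve(data.frame(mid_peep = c(5, 10),
                                       ri_ratio = c(1, 2))),
               "at least 3")
  expect_error(fit_ri_curve(data.frame(mid_peep = rep(7, 4),
                                       ri_ratio = 1:4)),
               "identical")
})

test_that("equal sigmas reproduce the unweighted fit", {
  set.seed(5)
  pts <- ri_points(0.2, -0.008)
  pts$ri_ratio <- pts$ri_ratio + rnorm(5, 0, 0.1)
  f1 <- fit_ri_curve(pts)
  pts$sigma <- 0.37
  f2 <- fit_ri_curve(pts)
  expect_equal(f1$b1, f2$b1, tolerance = 1e-10)
  expect_equal(f1$b2, f2$b2, tolerance = 1e-10)
})

test_that("the closed form attains the brute-force grid optimum", {
  # progressive-refinement grid search down to 1e-4 resolution in b1 and b2;
  # valid as a global search because the objective is convex
  grid_oracle <- function(x, y, w) {
    obj <- function(b1, b2) {
      colSums(w * (y - outer(x, b1) - outer(x^2, b2))^2)
    }
    lo <- c(-1, -0.1); hi <- c(1, 0.1)
    for (stage in 1:5) {
      b1g <- seq(lo[1], hi[1], length.out = 41)
      b2g <- seq(lo[2], hi[2], length.out = 41)
      vals <- sapply(b2g, function(b2) obj(b1g, rep(b2, length(b1g))))
      ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
      best <- c(b1g[ix[1]], b2g[ix[2]])
      span <- c(b1g[2] - b1g[1], b2g[2] - b2g[1])
      lo <- best - 2 * span; hi <- best + 2 * span
    }
    list(par = best, value = min(vals))
  }
  set.seed(77)
  for (i in 1:50) {
    n <- sample(4:7, 1)
    x <- sort(runif(n, 1, 16))
    y <- runif(1, -0.5, 0.5) * x + runif(1, -0.05, 0.05) * x^2 +
      rnorm(n, 0, 0.2)
    sg <- runif(n, 0.05, 0.5)
    fit <- fit_ri_curve(data.frame(mid_peep = x, ri_ratio = y, sigma = sg))
    w <- 1 / sg^2
    obj_closed <- sum(w * (y - fit$b1 * x - fit$b2 * x^2)^2)
    oracle <- grid_oracle(x, y, w)
    expect_lte(obj_closed, oracle$value + 1e-9)
  }
})

test_that("the closed form matches an independent regression route", {
  set.seed(13)
  x <- c(2.5, 6.5, 9, 11.5, 14)
  y <- 0.25 * x - 0.009 * x^2 + rnorm(5, 0, 0.15)
  fit <- fit_ri_curve(data.frame(mid_peep = x, ri_ratio = y))
  ref <- stats::lm(y ~ 0 + x + I(x^2))
  expect_equal(fit$b1, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(fit$b2, unname(coef(ref)[2]), tolerance = 1e-10)
})

test_that("the usability gate names the failing check", {
  good <- fit_ri_curve(ri_points(0.3, -0.01))
  expect_true(gof_gate(good)$usable)
  expect_equal(gof_gate(good)$reason, "")

  # strong lack of fit: a step pattern no parabola through 0 matches
  set.seed(3)
  bad <- fit_ri_curve(data.frame(mid_peep = c(2.5, 6.5, 9, 11.5, 14),
                                 ri_ratio = c(3, -2, 3, -2, 3),
                                 sigma = 0.05))
  expect_false(bad$gof_pass)
  expect_match(gof_gate(bad)$reason, "GOF_FAIL")
  expect_equal(bad$shape, "indeterminate")

  # plausible-looking parabola with a far vertex: implausible flag
  far <- fit_ri_curve(ri_points(4, -0.05))  # vertex at 40, RI(20) = 60
  expect_true(far$implausible)
  expect_match(gof_gate(far)$reason, "IMPLAUSIBLE")
})

test_that("prediction honors the origin, the gate and the extrapolation bound", {
  fit <- fit_ri_curve(ri_points(0.3, -0.01))
  expect_equal(predict_ri(fit, 15), 2.25, tolerance = 1e-9)
  expect_identical(predict_ri(fit, 0), 0)
  expect_error(predict_ri(fit, 30), "outside")

  set.seed(3)
  bad <- fit_ri_curve(data.frame(mid_peep = c(2.5, 6.5, 9, 11.5, 14),
                                 ri_ratio = c(3, -2, 3, -2, 3),
                                 sigma = 0.05))
  expect_error(predict_ri(bad, 10), "refusing")
})

test_that("propagated R/I sigmas follow the recruited-volume chain", {
  tr <- make_trial(crs = 40)
  ranges <- compute_granular_recruitment(tr)
  sg <- ri_point_sigma(ranges, 25)
  expect_equal(sg, 25 / (ranges$delta_peep * ranges$crs_low))
  V <- ri_point_covariance(ranges, 25)
  expect_equal(diag(V), sg^2, tolerance = 1e-12)
  # adjacent ranges share a node: negative covariance; zeep range independent
  expect_lt(V[1, 2], 0)
  expect_equal(V[1, 2],
               -(25^2 / 2) / (2 * ranges$crs_low[1] * 3 * ranges$crs_low[2]),
               tolerance = 1e-12)
  expect_equal(V[4, 5], 0)
  expect_equal(V, t(V))
})
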