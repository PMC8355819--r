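times15 <- (0:14) / 7   # 21-phase sequence at 20/min: 15 samples over 2 s

test_that("block downsampling averages intensity and votes the mask", {
  arr <- array(0, c(4, 4, 4, 2))
  arr[1:2, 1:2, 1:2, ] <- -400
  arr[3:4, 1:2, 1:2, ] <- rep(c(-400, -200), each = 2)  # 4x -400, 4x -200
  mask <- array(TRUE, c(4, 4, 4))
  mask[1:2, 3:4, 1:2] <- c(TRUE, FALSE, FALSE, FALSE,
                           FALSE, FALSE, FALSE, TRUE)  # 2/8 in mask
  g <- NULL
  sq <- aligned_sequence(arr, 0.6, mask, g)
  ds <- block_downsample(sq, 2)
  expect_equal(dim(ds$intensity), c(2, 2, 2, 2))
  expect_equal(ds$intensity[1, 1, 1, 1], -400)       # constant block
  expect_equal(ds$intensity[2, 1, 1, 1], -300)       # mean of -400/-200
  expect_equal(ds$spacing_mm, rep(1.2, 3))
  expect_false(ds$mask[1, 2, 1])                     # 2/8 < majority
  expect_true(ds$mask[1, 1, 1])
  expect_identical(block_downsample(sq, 1), sq)      # identity
  expect_error(block_downsample(sq, 5), "exceeds")
})

test_that("noiseless series are recovered to high relative accuracy", {
  y <- -250 + (-400 - -250) * exp(-times15 / 0.4)
  f <- fit_exponential(times15, y, t_exp_s = 2)
  expect_equal(f$d0, -400, tolerance = 1e-6)
  expect_equal(f$dinf, -250, tolerance = 1e-6)
  expect_equal(f$tau_s, 0.4, tolerance = 1e-6)
  expect_true(f$significant)
  expect_false(f$at_bound)
  # model value at t = 0 is D0 exactly; hand value at t = tau
  expect_equal(f$d0 + (f$dinf - f$d0) * (1 - exp(-0.4 / f$tau_s)),
               -305.1819, tolerance = 1e-3)
  # derived end-expiratory quantities
  expect_equal(f$d_ee, -250 + (-150) * exp(-2 / 0.4), tolerance = 1e-6)
  expect_equal(f$intratidal_change + f$nonequilibrated_change,
               f$dinf - f$d0, tolerance = 1e-9)
})

test_that("constant series yield D0 = Dinf and are non-significant", {
  f <- fit_exponential(times15, rep(-412.5, 15))
  expect_equal(f$d0, -412.5)
  expect_equal(f$dinf, -412.5)
  expect_true(is.na(f$tau_s))
  expect_equal(f$f_stat, 0)
  expect_equal(f$p_value, 1)
  expect_false(f$significant)
})

test_that("fitter input contracts are enforced", {
  expect_error(fit_exponential(c(0, 1, 2), c(1, 2, 3)), "at least 4")
  expect_error(fit_exponential(c(1, 2, 3, 4), 1:4), "start at 0")
  expect_error(fit_exponential(c(0, 1, 1, 2), 1:4), "strictly increasing")
  expect_error(fit_exponential(0:3, 1:3), "equal length")
})

test_that("F statistic and p-value match independent oracles", {
  # hand arithmetic: n = 15, sse_mean = 100, sse_model = 10
  r <- f_significance(list(sse_mean = 100, sse_model = 10), 15)
  expect_equal(r$f_stat, 54)
  expect_equal(r$p_value, oracle_f_tail(54, 2, 12), tolerance = 1e-8)
  # no improvement
  r0 <- f_significance(list(sse_mean = 100, sse_model = 100), 15)
  expect_equal(r0$f_stat, 0)
  expect_equal(r0$p_value, 1)
  # perfect fit
  rp <- f_significance(list(sse_mean = 100, sse_model = 0), 15)
  expect_equal(rp$p_value, 0)
  expect_error(f_significance(list(sse_mean = 1, sse_model = 1), 3),
               "more than 3")
})

test_that("the F-filter's null rejection rate does not exceed nominal", {
  # profiling the nonlinear tau makes the nominal F(2, n-3) reference
  # approximate; the realized null rejection is conservative
  set.seed(401)
  arr <- array(stats::rnorm(10 * 10 * 20 * 21, -300, 15),
               c(10, 10, 20, 21))
  g <- build_phase_grid(21, 20, c(1, 2), 1)
  sq <- aligned_sequence(arr, 1.2, array(TRUE, c(10, 10, 20)), g)
  fits <- suppressMessages(fit_all_voxels(sq, g))
  rate <- mean(fits$significant)
  expect_lt(rate, 0.065)
  expect_gt(rate, 0.005)
})

test_that("optimizer SSE beats an independent profiled grid-search oracle", {
  set.seed(402)
  n_vox <- 60
  worse <- 0
  for (i in seq_len(n_vox)) {
    d0 <- runif(1, -900, -200)
    amp <- runif(1, -50, 200)
    tau <- 10^runif(1, -1, 0.3)
    y <- (d0 + amp) - amp * exp(-times15 / tau) +
      rnorm(15, 0, runif(1, 0, 20))
    f <- fit_exponential(times15, y)
    o <- oracle_profiled_sse(times15, y)
    if (f$sse_model > o + 1e-8 * (1 + o)) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("fit agrees with an independent Levenberg-Marquardt implementation", {
  skip_if_not_installed("minpack.lm")
  set.seed(403)
  y <- -350 + 120 * exp(-times15 / 0.6) + rnorm(15, 0, 10)
  f <- fit_exponential(times15, y)
  nls_fit <- minpack.lm::nlsLM(
    y ~ dinf + (d0 - dinf) * exp(-times15 / tau),
    start = list(d0 = y[1], dinf = y[15], tau = 0.5),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  sse_lm <- sum(stats::residuals(nls_fit)^2)
  expect_lte(f$sse_model, sse_lm + 1e-6 * (1 + sse_lm))
  expect_equal(f$tau_s, unname(stats::coef(nls_fit)["tau"]),
               tolerance = 1e-3)
})

test_that("whole-map fits recover noiseless phantom truth", {
  ph <- clean_phantom_small()
  fits <- fit_cached("clean24", ph$seq)
  tr <- ph$truth
  amp <- (tr$dinf_map - tr$d0_map)[fits$voxel]
  nc <- abs(amp) > 1e-9
  expect_true(all(fits$significant[nc]))
  err <- abs(fits$tau_s[nc] - tr$tau_map[fits$voxel][nc])
  expect_lt(max(err), 1e-4)
  # D_EE always lies between D0 and Dinf (monotone model prediction)
  sig <- fits$significant
  expect_true(all(
    fits$d_ee[sig] >= pmin(fits$d0[sig], fits$dinf[sig]) - 1e-9 &
    fits$d_ee[sig] <= pmax(fits$d0[sig], fits$dinf[sig]) + 1e-9))
})

test_that("volume time constant and mechanics come off the trace", {
  spec <- phantom_spec(grid_shape = c(8, 8, 8), seed = 4)
  tr <- generate_parameter_fields(spec)
  trc <- render_ventilator_trace(tr, spec)
  mech <- fit_volume_time_constant(trc)
  expect_equal(mech$tau_volume_s, spec$volume_trace_tau_s,
               tolerance = 1e-3)
  expect_equal(mech$driving_pressure_cmh2o, 20.8 - 8.1, tolerance = 1e-9)
  expect_equal(mech$dynamic_elastance_cmh2o_per_l,
               mech$driving_pressure_cmh2o / mech$tidal_volume_l)

  flat <- trc
  flat$volume_ml <- 0
  expect_error(fit_volume_time_constant(flat), "zero amplitude")
  still <- trc
  still$pressure_cmh2o <- 10
  expect_error(fit_volume_time_constant(still), "flat")
})

test_that("dynamic elastance is the pressure-volume quotient", {
  expect_equal(dynamic_elastance(12, 0.1), 120)
  expect_equal(dynamic_elastance(0, 0.5), 0)
  expect_equal(dynamic_elastance(12.7, 0.0888), 143.018, tolerance = 1e-4)
  expect_error(dynamic_elastance(10, 0), "tidal_volume")
  expect_error(dynamic_elastance(-1, 0.1), ">= 0")
})
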