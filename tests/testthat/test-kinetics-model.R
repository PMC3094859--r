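test_that("DIRF is a unit mono-exponential impulse response", {
  expect_equal(dirf_response(0, 18), 1)
  expect_equal(dirf_response(18, 18), 0.5)
  expect_equal(dirf_response(36, 18), 0.25)
  expect_error(dirf_response(-1, 18), ">= 0")
  expect_error(dirf_response(1, 0), "> 0")
})

test_that("forward model limits behave: no efflux and instantaneous DIRF", {
  tt <- seq(0, 200, by = 10)
  p0 <- kinetic_model_params(C = 0, viability_half_life = Inf)
  expect_equal(forward_model(p0, tt)$measured, rep(1, length(tt)))
  # DIRF half-life -> 0: interstitial label clears instantly
  pfast <- kinetic_model_params(C = 0.01, dirf_half_life = 1e-9,
                                viability_half_life = 100)
  m <- forward_model(pfast, tt)
  expect_equal(m$measured, m$intracellular, tolerance = 1e-9)
})

test_that("closed form matches the trapezoidal convolution to 1e-6", {
  tt <- seq(0, 100, by = 0.01)
  for (th in c(50, 200, 1000)) {
    p <- kinetic_model_params(C = log(2) / 1434, dirf_half_life = 18,
                              viability_half_life = th)
    cf <- forward_model(p, tt)$measured
    nm <- forward_model(p, tt, method = "numeric")$measured
    expect_lt(max(abs(cf - nm) / cf), 1e-6)
  }
  # degenerate equal-rate branch agrees with the convolution too
  lam <- log(2) / 100
  peq <- kinetic_model_params(C = lam, dirf_half_life = log(2) / lam,
                              viability_half_life = Inf)
  cf <- forward_model(peq, seq(0, 100, 0.05))$measured
  nm <- forward_model(peq, seq(0, 100, 0.05), method = "numeric")$measured
  expect_lt(max(abs(cf - nm) / cf), 1e-6)
})

test_that("an arbitrary sampled impulse response can replace the DIRF", {
  p <- kinetic_model_params(C = 0.002, dirf_half_life = 18,
                            viability_half_life = 300)
  tt <- seq(0, 50, by = 0.05)
  via_irf <- forward_model(p, tt, method = "numeric",
                           irf = function(l) dirf_response(l, 18))$measured
  expect_equal(via_irf, forward_model(p, tt)$measured, tolerance = 1e-6)
  expect_error(forward_model(p, tt, irf = function(l) exp(-l)),
               "numeric")
})

test_that("compartments conserve label and measured signal never rises", {
  tt <- seq(0, 500, by = 2.5)
  set.seed(42)
  for (i in 1:10) {
    p <- kinetic_model_params(C = runif(1, 0, 0.01),
                              dirf_half_life = runif(1, 5, 40),
                              viability_half_life = runif(1, 30, 2000))
    fm <- forward_model(p, tt)
    expect_lt(max(abs(fm$intracellular + fm$interstitial + fm$cleared - 1)),
              1e-9)
    expect_true(all(fm$intracellular >= 0 & fm$interstitial >= 0 &
                      fm$cleared >= -1e-12))
    expect_true(all(diff(fm$measured) <= 1e-12))
  }
})

test_that("viability inversion recovers the truth on noiseless curves", {
  C <- log(2) / 1434
  sched <- acquisition_schedule()
  for (th in exp(seq(log(30), log(1200), length.out = 7))) {
    p <- kinetic_model_params(C = C, dirf_half_life = 18,
                              viability_half_life = th)
    y <- forward_model(p, sched)$measured
    inv <- invert_viability(tac(sched, y), C = C, dirf_half_life = 18)
    expect_lt(abs(inv$viability_half_life - th) / th, 0.01)
  }
})

test_that("inversion flags estimates outside the validity window", {
  C <- log(2) / 1434
  sched <- acquisition_schedule()
  # clearance faster than the 20 h lower bound: model not applicable
  p <- kinetic_model_params(C = C, dirf_half_life = 18,
                            viability_half_life = 10)
  y <- forward_model(p, sched)$measured
  inv <- invert_viability(tac(sched, y), C = C, dirf_half_life = 18)
  expect_false(inv$in_bounds)
  expect_false(inv$valid)
  # constant curve with C = 0: estimate runs to the search ceiling
  flat <- tac(c(0, 24, 168, 504), rep(1, 4))
  inv2 <- invert_viability(flat, C = 0, dirf_half_life = 18)
  expect_false(inv2$valid)
  expect_identical(inv2$status, "at_search_boundary")
  expect_gt(inv2$viability_half_life, inv2$upper_bound)
  # short TACs are rejected outright
  expect_error(invert_viability(tac(c(0, 1), c(1, 0.9)), C = C,
                                dirf_half_life = 18), "3 points")
})

test_that("the 37-day preset tightens the upper validity bound", {
  p60 <- kinetic_model_params()
  p37 <- kinetic_model_params(bounds_preset = "37d")
  expect_equal(p60$upper_bound, 1440)
  expect_equal(p37$upper_bound, 888)
  C <- log(2) / 1434
  sched <- acquisition_schedule()
  th <- 1000   # inside 60 d, outside 37 d
  y <- forward_model(kinetic_model_params(C = C, dirf_half_life = 18,
                                          viability_half_life = th),
                     sched)$measured
  x <- tac(sched, y)
  expect_true(invert_viability(x, C, 18, bounds = p60)$in_bounds)
  expect_false(invert_viability(x, C, 18, bounds = p37)$in_bounds)
})

test_that("with immortal cells the late slope approaches the leakage rate", {
  C <- log(2) / 1434
  p <- kinetic_model_params(C = C, dirf_half_life = 18,
                            viability_half_life = Inf)
  tt <- seq(500, 5000, by = 100)
  m <- forward_model(p, tt)$measured
  slope <- -coef(lm(log(m) ~ tt))[[2]]
  expect_equal(slope, C, tolerance = 0.01)
})

test_that("viable-to-debris clearance ratio is plain division", {
  expect_equal(leakage_to_dirf_ratio(790, 10), 79)
  expect_equal(leakage_to_dirf_ratio(18, 18), 1)
  expect_error(leakage_to_dirf_ratio(100, 0), "> 0")
})
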