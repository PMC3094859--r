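test_that("half-life conversion matches the tabulated reference values", {
  expect_equal(round(half_life(0.0001245)), 5567)
  expect_equal(round(half_life(0.0005308)), 1306)
  expect_equal(half_life(log(2)), 1)
  # identity: rate = ln2 / T recovers T
  for (T in c(0.3, 1, 18, 537, 5567)) expect_equal(half_life(log(2) / T), T)
  expect_error(half_life(0), "> 0")
})

test_that("fraction normalization is exact and closed form", {
  expect_equal(normalize_fractions(37.9, 62.1), c(a_pct = 37.9, c_pct = 62.1))
  expect_equal(normalize_fractions(1, 1), c(a_pct = 50, c_pct = 50))
  expect_equal(normalize_fractions(0, 5), c(a_pct = 0, c_pct = 100))
  set.seed(1)
  for (i in 1:20) {
    fr <- normalize_fractions(runif(1, 0, 10), runif(1, 0.1, 10))
    expect_identical(sum(fr), 100)
  }
  expect_error(normalize_fractions(0, 0), "zero")
})

test_that("noiseless fits recover the generating parameters to 0.1%", {
  sched <- acquisition_schedule()
  p <- ref_epi1_params()
  x <- decay_correct(simulate_tac(p, sched))
  f <- fit_biexponential(x)
  expect_identical(f$model, "biexponential")
  expect_equal(f$a_pct, 37.9, tolerance = 1e-3)
  expect_equal(f$b, 0.3712, tolerance = 1e-3)
  expect_equal(f$c_pct, 62.1, tolerance = 1e-3)
  expect_equal(f$d, 0.0012930, tolerance = 1e-3)
  expect_gt(f$b, f$d)
  expect_equal(f$a_pct + f$c_pct, 100)
})

test_that("single-exponential washout falls back to a monoexponential fit", {
  sched <- acquisition_schedule()
  p <- clearance_params(a = 0, b = NA, c = 100, d = 0.0005308)
  x <- decay_correct(simulate_tac(p, sched))
  f <- fit_biexponential(x)
  expect_identical(f$model, "monoexponential")
  expect_equal(f$c_pct, 100)
  expect_true(is.na(f$a_pct))
  expect_equal(f$d, 0.0005308, tolerance = 1e-3)
  expect_equal(round(f$t_half_long), 1306)
})

test_that("a constant TAC is flagged as a zero-rate boundary fit", {
  x <- tac(acquisition_schedule(), rep(5, length(acquisition_schedule())))
  f <- fit_biexponential(x)
  expect_identical(f$model, "monoexponential")
  expect_true("rate_at_zero_boundary" %in% f$status)
  expect_identical(f$t_half_long, Inf)
})

test_that("sparse or short-only sampling degrades gracefully", {
  # no late coverage: monoexponential path, never a silent biexponential
  x <- decay_correct(simulate_tac(ref_epi1_params(), c(0, 1, 2, 3, 4, 5)))
  expect_identical(fit_biexponential(x)$model, "monoexponential")
  expect_error(fit_biexponential(tac(c(0, 1), c(2, 1))), "3 points")
})

test_that("fitted rates always come back ordered b > d", {
  sched <- acquisition_schedule()
  set.seed(7)
  for (i in 1:10) {
    p <- random_clearance_params()
    f <- fit_biexponential(decay_correct(simulate_tac(p, sched)))
    if (f$model == "biexponential") {
      expect_gt(f$b, f$d)
      expect_lt(f$t_half_short, f$t_half_long)
      expect_equal(f$b, p$b, tolerance = 1e-3)
      expect_equal(f$d, p$d, tolerance = 1e-3)
    }
  }
})

test_that("Poisson-weighted fits keep median rate errors within 15%", {
  sched <- acquisition_schedule()
  set.seed(99)
  errs <- replicate(30, {
    p <- random_clearance_params()
    s <- sample.int(1e6, 1)
    x <- decay_correct(simulate_tac(p, sched, noise = "poisson",
                                    peak_counts = 1e4, seed = s))
    f <- fit_biexponential(x, weights = "poisson")
    if (f$model != "biexponential") return(c(NA_real_, NA_real_))
    c(abs(f$b - p$b) / p$b, abs(f$d - p$d) / p$d)
  })
  expect_lt(median(errs[1, ], na.rm = TRUE), 0.15)
  expect_lt(median(errs[2, ], na.rm = TRUE), 0.15)
})

test_that("fit tables carry the reporting columns", {
  sched <- acquisition_schedule()
  fits <- list(s1 = fit_biexponential(decay_correct(
    simulate_tac(ref_epi1_params(), sched))))
  tab <- fits_to_table(fits, group = "epicardial")
  expect_identical(names(tab),
                   c("subject", "group", "a", "b", "c", "d", "a_pct",
                     "c_pct", "t12s_hours", "t12l_hours", "model", "rss"))
  expect_identical(tab$subject, "s1")
})
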