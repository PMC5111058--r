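test_that("single-filament MSD reproduces hand-computed small-n values", {
  r <- rates_slow_restart()
  msd <- msd_single(r, initial_state(1), n_max = 2)
  # P1 = 0.9, P2 = 0.8101, G(1) = 0.9 -> 0.9 and 0.9 + 0.8101 + 2*0.9*0.9
  expect_equal(msd$msd, c(0.9, 3.3301), tolerance = 1e-12)
})

test_that("pure ballistic and immediately-trapped limits", {
  msd <- msd_single(transition_rates(0, 1), initial_state(1), n_max = 20)
  expect_equal(msd$msd, (1:20)^2)
  # kappa_w = 1 with a sure motion start: the first transition precedes the
  # first displacement, so the walker is trapped before ever moving
  msd0 <- msd_single(transition_rates(1, 0), initial_state(1), n_max = 10)
  expect_equal(msd0$msd, rep(0, 10))
})

test_that("analytic engine matches the enumeration oracle", {
  set.seed(101)
  for (i in 1:60) {
    r <- transition_rates(draw_probability(), draw_probability())
    init <- initial_state(draw_probability())
    steps <- step_custom(runif(1, 0.5, 2), 1 + rexp(1))
    n <- sample(1:12, 1)
    ana <- msd_single(r, init, steps, n)$msd[n]
    expect_equal(ana, enumerate_msd_single(r, init, steps, n),
                 tolerance = 1e-12)
  }
})

test_that("MSD is monotone in n and in the switching probabilities", {
  grid <- c(0.05, 0.3, 0.7, 1)
  for (kw in grid) for (km in grid) {
    msd <- msd_single(transition_rates(kw, km), initial_state(0.5),
                      n_max = 200)$msd
    expect_true(all(diff(msd) >= -1e-12))
  }
  # pointwise non-decreasing in kappa_m, non-increasing in kappa_w
  base <- msd_single(transition_rates(0.3, 0.3), initial_state(0.5),
                     n_max = 100)$msd
  more_restart <- msd_single(transition_rates(0.3, 0.6), initial_state(0.5),
                             n_max = 100)$msd
  more_pause <- msd_single(transition_rates(0.6, 0.3), initial_state(0.5),
                           n_max = 100)$msd
  expect_true(all(more_restart >= base - 1e-12))
  expect_true(all(more_pause <= base + 1e-12))
})

test_that("initial exponent follows the two-point power-law fit", {
  expect_equal(initial_exponent_single(transition_rates(0, 1),
                                       initial_state(1)), 2)
  expect_equal(initial_exponent_single(rates_slow_restart(),
                                       initial_state(1)),
               log2(3.3301 / 0.9), tolerance = 1e-12)
  # waiting-start cascade P_i = 1 - (1 - kappa_m)^i, G = 1
  r <- transition_rates(0, 0.001)
  expect_equal(initial_exponent_single(r, initial_state(0)),
               log2(0.004999 / 0.001), tolerance = 1e-9)
  expect_error(initial_exponent_single(transition_rates(1, 0),
                                       initial_state(1)), "undefined")
})

test_that("asymptotic ballistic prefactor is the squared mean drift", {
  expect_equal(asymptotic_msd_prefactor_single(transition_rates(0, 0.5)), 1)
  expect_equal(asymptotic_msd_prefactor_single(rates_symmetric()), 1 / 4)
  expect_equal(asymptotic_msd_prefactor_single(rates_slow_restart()),
               (0.001 / 0.101)^2)
  # cross-check against the engine deep in the ballistic regime
  r <- rates_slow_restart()
  n <- 1e6
  msd_n <- msd_single(r, initial_state(1), n_max = n)$msd[n]
  expect_equal(msd_n / n^2, asymptotic_msd_prefactor_single(r),
               tolerance = 1e-2)
  expect_error(asymptotic_msd_prefactor_single(transition_rates(0, 0)),
               "freezes")
})

test_that("waiting-start continuous MSD matches its defining integral", {
  # closed form vs numerical quadrature of int kappa e^(-kappa t0) v^2 (t-t0)^2
  for (kappa in c(0.5, 1, 2)) for (t in c(0.3, 1, 5)) {
    quad <- stats::integrate(
      function(t0) kappa * exp(-kappa * t0) * (t - t0)^2, 0, t
    )$value
    expect_equal(waiting_start_msd_continuous(kappa, 1, t), quad,
                 tolerance = 1e-8)
  }
  expect_equal(waiting_start_msd_continuous(1, 1, 1),
               1 - 2 + 2 - 2 * exp(-1), tolerance = 1e-12)
  # large-t limit: delayed ballistic motion
  t <- 1e4
  expect_equal(waiting_start_msd_continuous(1, 2, t),
               4 * ((t - 1)^2 + 1), tolerance = 1e-9)
  expect_error(waiting_start_msd_continuous(-1, 1, 1), "positive")
})

test_that("super-ballistic transients occur for strongly sub-stationary starts", {
  r <- transition_rates(0.1, 0.001)
  s <- stationary_occupancy(r)[["P_m"]]
  # an all-waiting start injects walkers into ballistic motion: alpha > 2
  msd <- msd_single(r, initial_state(0), n_max = 5000)
  expect_gt(max(alpha_series(msd)$alpha), 2)
  # stationary or over-populated starts never exceed the ballistic exponent
  for (q0 in c(s, 0.5, 1)) {
    msd <- msd_single(r, initial_state(q0), n_max = 5000)
    expect_lte(max(alpha_series(msd)$alpha), 2 + 1e-9)
  }
  # close to the stationary start the injection transient is too weak to
  # push alpha above 2 even though the acceleration is present
  amax_near <- max(alpha_series(
    msd_single(r, initial_state(s / 2), n_max = 5000))$alpha)
  expect_lt(amax_near, 2)
  expect_gt(amax_near, 1.9)
})
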