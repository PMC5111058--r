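test_that("network MSD reproduces hand-computed small-n values", {
  # single-state persistent walk: g(k) = A^k
  m <- network_model(transition_rates(0, 1), A = 0.5)
  expect_equal(msd_network(m, 3)$msd, c(1, 3, 5.5), tolerance = 1e-12)
  # isotropic non-persistent single-state walk is diffusive at every n
  m0 <- network_model(transition_rates(0, 1), A = 0)
  expect_equal(msd_network(m0, 50)$msd, as.numeric(1:50), tolerance = 1e-12)
})

test_that("analytic network engine matches the enumeration oracle", {
  set.seed(202)
  for (i in 1:60) {
    r <- transition_rates(draw_probability(), draw_probability())
    init <- initial_state(draw_probability())
    steps <- step_custom(runif(1, 0.5, 2), 1 + rexp(1))
    m <- network_model(r, init, steps, A = runif(1, -1, 1))
    n <- sample(1:10, 1)
    expect_equal(msd_network(m, n)$msd[n], enumerate_msd_network(m, n),
                 tolerance = 1e-12)
  }
})

test_that("A = 1 reduces the network engine to the single-filament engine", {
  set.seed(303)
  for (i in 1:20) {
    r <- transition_rates(runif(1), runif(1))
    init <- initial_state(runif(1))
    steps <- step_custom(runif(1, 0.5, 2), 1 + rexp(1))
    m <- network_model(r, init, steps, A = 1)
    expect_equal(msd_network(m, 300)$msd,
                 msd_single(r, init, steps, 300)$msd, tolerance = 1e-12)
  }
})

test_that("MSD depends on the turn distribution only through A", {
  r <- transition_rates(0.2, 0.4)
  # two very different symmetric turn models with the same mean cosine
  t1 <- turn_delta(pi / 3)                       # cos = 1/2
  t2 <- turn_discrete(c(0, pi, 0), c(3, 1, 0))   # (3*1 - 1)/4 = 1/2
  m1 <- network_model(r, turns = t1, p = 0)
  m2 <- network_model(r, turns = t2, p = 0)
  expect_equal(m1$A, m2$A)
  expect_equal(msd_network(m1, 100)$msd, msd_network(m2, 100)$msd)
})

test_that("initial network exponent covers the printed special cases", {
  # non-processive isotropic single-state: diffusive from the start
  expect_equal(initial_exponent_network(
    network_model(transition_rates(0, 1), A = 0)), 1)
  expect_equal(initial_exponent_network(
    network_model(transition_rates(0, 1), A = 1)), 2)
  # square lattice at zero processivity: log2(2 + 2A/lambda), A = 1/3
  m <- network_model(transition_rates(0, 1),
                     turns = square_lattice_turns(), p = 0)
  expect_equal(initial_exponent_network(m), log2(8 / 3), tolerance = 1e-12)
  # general single-state law log2(2 + 2 A / lambda)
  m2 <- network_model(transition_rates(0, 1), steps = step_exponential(),
                      A = 0.7)
  expect_equal(initial_exponent_network(m2), log2(2 + 2 * 0.7 / 2),
               tolerance = 1e-12)
})

test_that("Gamma scale factor has the renewal closed form", {
  expect_equal(gamma_scale(1, 0), 1)
  expect_equal(gamma_scale(1.7, 0), 1.7)
  expect_equal(gamma_scale(1, 0.5), 3)
  expect_gt(gamma_scale(1, 0.999), 1000)
  expect_error(gamma_scale(1, 1), "diverges")
  expect_error(gamma_scale(0.5, 0), "lambda")
})

test_that("asymptotic diffusion constant matches the large-n MSD slope", {
  m <- network_model(transition_rates(0.05, 0.05), initial_state(1),
                     A = 0.5)
  d <- asymptotic_diffusion(m, v = 1)
  n <- 1e5
  slope <- msd_network(m, n)$msd[n] / n     # length^2 per step; tick = <l>/v
  expect_equal(slope / 4, d, tolerance = 1e-2)
  # symmetric isotropic case: D = v <l> / 8
  m0 <- network_model(transition_rates(0.3, 0.3), A = 0)
  expect_equal(asymptotic_diffusion(m0, v = 2), 2 / 8)
  expect_error(asymptotic_diffusion(
    network_model(transition_rates(0.1, 0.1), A = 1)), "diverges")
})

test_that("D_inf is independent of the initial conditions", {
  r <- transition_rates(0.2, 0.1)
  d <- sapply(c(0, 0.5, 1), function(q0) {
    asymptotic_diffusion(network_model(r, initial_state(q0), A = 0.3))
  })
  expect_equal(d[1], d[2])
  expect_equal(d[1], d[3])
  # and the large-n slopes agree across initial conditions
  n <- 2e5
  s0 <- msd_network(network_model(r, initial_state(0), A = 0.3), n)$msd[n]
  s1 <- msd_network(network_model(r, initial_state(1), A = 0.3), n)$msd[n]
  expect_equal(s0 / n, s1 / n, tolerance = 1e-2)
})

test_that("long-time network dynamics is diffusive for any A < 1", {
  for (A in c(-0.5, 0, 0.5, 0.95)) {
    m <- network_model(transition_rates(0.1, 0.05), initial_state(1), A = A)
    a <- alpha_series(msd_network(m, 2e4))
    expect_equal(a$alpha[nrow(a)], 1, tolerance = 1e-2)
  }
})
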