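# Four-state HHM cross-bridge kinetics over the bond-extension coordinate:
# rate functions, isometric steady states, transport-reaction stepping, and
# the contractile force integral.

test_that("strain-dependent rate functions follow the piecewise forms", {
  p <- rate_parameters(k1 = 0.025, g1 = 0.1)
  r <- rate_functions(c(-0.5, 0, 0.5, 1, 1.5), p)
  # no attachment outside the powerstroke window [0, h]
  expect_equal(r$fp[1], 0)
  expect_equal(r$fp[5], 0)
  # linear-in-x branches vanish at x = 0 and reach their coefficients at h
  expect_equal(r$fp[2], 0)
  expect_equal(r$gp[2], 0)
  expect_equal(r$g[2], 0)
  expect_equal(r$fp[4], p$fp1)
  expect_equal(r$g[4], p$g1)
  # constant fast detachment for compressed bridges
  expect_equal(r$gp[1], p$gp_neg)
  expect_equal(r$g[1], p$g_neg)
})

test_that("rate parameter validation rejects bad inputs", {
  expect_error(rate_parameters(k1 = -0.1), "non-negative")
  expect_error(rate_parameters(h = 0), "positive")
})

test_that("steady state is fully detached without phosphorylation", {
  p <- rate_parameters(k1 = 0)
  ss <- steady_state_populations(p, quiet = TRUE)
  expect_equal(max(abs(ss$nM - 1)), 0)
  expect_equal(max(ss$nMp + ss$nAMp + ss$nAM), 0)
})

test_that("without attachment the detached pool follows the k1/k2 balance", {
  p <- rate_parameters(k1 = 0.02, k2 = 0.05, fp1 = 0)
  ss <- steady_state_populations(p, quiet = TRUE)
  expect_equal(max(ss$nAMp + ss$nAM), 0)
  expect_equal(ss$nMp / ss$nM, rep(p$k1 / p$k2, length(ss$x)),
               tolerance = 1e-12)
})

test_that("closed-form steady state matches long-time ODE integration", {
  p <- rate_parameters(k1 = 0.025)
  ss <- steady_state_populations(p, quiet = TRUE)
  for (x in c(-0.5, 0.25, 0.5, 0.75, 1.0)) {
    sol <- ode_oracle_at_x(x, p, times = c(0, 20000))
    i <- which.min(abs(ss$x - x))
    got <- c(ss$nM[i], ss$nMp[i], ss$nAMp[i], ss$nAM[i])
    want <- as.numeric(sol[2, 2:5])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("steady-state fractions sum to one and stay in [0, 1]", {
  for (k1 in c(0.005, 0.025, 0.05, 0.35)) {
    p <- rate_parameters(k1 = k1)
    ss <- steady_state_populations(p, quiet = TRUE)
    expect_lt(max(abs(ss$nM + ss$nMp + ss$nAMp + ss$nAM - 1)), 1e-12)
    expect_gte(min(ss$nM, ss$nMp, ss$nAMp, ss$nAM), 0)
    expect_lte(max(ss$nM, ss$nMp, ss$nAMp, ss$nAM), 1)
  }
})

test_that("pure advection shifts all fields exactly at integer Courant", {
  p <- rate_parameters(k1 = 0, k2 = 0, fp1 = 0, gp_neg = 0, gp1 = 0,
                       g1 = 0, g_neg = 0)
  pop <- small_pop(p)
  # place a bump in each field away from the boundaries
  bump <- exp(-((pop$x - 0.5) / 0.3)^2)
  pop$nAMp <- 0.3 * bump
  pop$nMp <- 0.2 * bump
  pop$nM <- 1 - pop$nMp - pop$nAMp
  k <- 12                       # shift by exactly k grid cells
  cc <- 1.3
  dt <- k * pop$dx / cc
  adv <- advance_populations(pop, p, c = cc, dt = dt)
  # c > 0 transports toward smaller x: field shifted left by k cells
  n <- length(pop$x)
  expect_equal(adv$nAMp[seq_len(n - k)], pop$nAMp[(k + 1):n],
               tolerance = 1e-12)
  expect_equal(adv$nMp[seq_len(n - k)], pop$nMp[(k + 1):n],
               tolerance = 1e-12)
  # inflow at the upwind boundary is fully detached
  expect_equal(adv$nM[(n - k + 1):n], rep(1, k), tolerance = 1e-12)
  # same shift in the other direction
  adv2 <- advance_populations(pop, p, c = -cc, dt = dt)
  expect_equal(adv2$nAMp[(k + 1):n], pop$nAMp[seq_len(n - k)],
               tolerance = 1e-12)
})

test_that("reaction-only stepping matches the dense ODE oracle", {
  p <- rate_parameters(k1 = 0.025)
  pop <- small_pop(p)
  T_end <- 40
  adv <- pop
  for (i in seq_len(80)) adv <- advance_populations(adv, p, c = 0, dt = 0.5)
  for (x in c(0.25, 0.75)) {
    sol <- ode_oracle_at_x(x, p, times = c(0, T_end))
    i <- which.min(abs(pop$x - x))
    got <- c(adv$nM[i], adv$nMp[i], adv$nAMp[i], adv$nAM[i])
    want <- as.numeric(sol[2, 2:5])
    expect_equal(got, want, tolerance = 2e-3)
  }
})

test_that("conservation holds pointwise through arbitrary step sequences", {
  set.seed(42)
  p <- rate_parameters(k1 = 0.025)
  pop <- small_pop(p)
  for (i in 1:30) {
    cc <- rnorm(1, 0, 2)
    dt <- runif(1, 0.005, 0.2)
    pop <- advance_populations(pop, p, c = cc, dt = dt)
    tot <- pop$nM + pop$nMp + pop$nAMp + pop$nAM
    expect_lt(max(abs(tot - 1)), 1e-8)
    expect_gte(min(pop$nM, pop$nMp, pop$nAMp, pop$nAM), 0)
  }
})

test_that("isometric integration converges to the closed-form steady state", {
  p <- rate_parameters(k1 = 0.025)
  pop <- small_pop(p)
  for (i in seq_len(4000)) pop <- advance_populations(pop, p, c = 0, dt = 1)
  ss <- steady_state_populations(p, pop = small_pop(p), quiet = TRUE)
  err <- max(abs(pop$nM - ss$nM), abs(pop$nMp - ss$nMp),
             abs(pop$nAMp - ss$nAMp), abs(pop$nAM - ss$nAM))
  expect_lt(err, 1e-5)
})

test_that("invalid advance arguments are rejected", {
  p <- rate_parameters()
  pop <- small_pop(p)
  expect_error(advance_populations(pop, p, c = 0, dt = 0), "positive")
  expect_error(advance_populations(pop, p, c = NA_real_, dt = 0.1), "finite")
})

test_that("active stress integral reproduces analytic cases", {
  p <- rate_parameters()
  pop <- small_pop(p, n_x = 501)
  # no attached bridges: zero stress
  expect_equal(active_stress(pop, beta = 100, kappa = 1)$A, 0)
  # indicator population on [0, h]: integral of x dx = h^2 / 2 (trapezoid
  # carries O(dx) edge error at the discontinuity)
  pop$nAMp <- as.numeric(pop$x >= 0 & pop$x <= 1)
  f <- active_stress(pop, beta = 1, kappa = 1)
  expect_equal(f$F_unit, 0.5, tolerance = 2e-2)
  expect_equal(f$A, f$F_unit * 1)
  # beta scales force into stress linearly
  f2 <- active_stress(pop, beta = 100, kappa = 1)
  expect_equal(f2$A, 100 * f$F_unit)
})

test_that("quadrature agrees with a 10x refined grid on smooth populations", {
  p <- rate_parameters()
  smooth_force <- function(n_x) {
    pop <- small_pop(p, n_x = n_x)
    bump <- function(c0, w, a) a * exp(-((pop$x - c0) / w)^2)
    pop$nAMp <- bump(0.45, 0.25, 0.35)
    pop$nAM <- bump(0.6, 0.4, 0.2)
    pop$nM <- 1 - pop$nAMp - pop$nAM
    active_stress(pop, kappa = 1)$F_unit
  }
  expect_equal(smooth_force(121), smooth_force(1201), tolerance = 1e-4)
})

test_that("isometric force is monotone in activation and latch detachment", {
  k1s <- seq(0, 0.05, length.out = 11)
  F <- vapply(k1s, function(k) {
    p <- rate_parameters(k1 = k)
    active_stress(steady_state_populations(p, quiet = TRUE),
                  kappa = 1)$F_unit
  }, numeric(1))
  expect_true(all(diff(F) >= -1e-12))
  # increasing g1 strictly reduces the steady latch-bridge pool
  am <- vapply(c(0.01, 0.1), function(g1) {
    p <- rate_parameters(k1 = 0.025, g1 = g1)
    ss <- steady_state_populations(p, quiet = TRUE)
    .trapz <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2
    .trapz(ss$x, ss$nAM)
  }, numeric(1))
  expect_lt(am[2], am[1])
})
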