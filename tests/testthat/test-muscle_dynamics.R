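# Hill-type MTU: activation dynamics, curve anchors, contraction step.

test_that("activation rate follows the asymmetric first-order law", {
  expect_equal(activation_rate(0.3, 0.3), 0)
  expect_equal(activation_rate(1, 0, tau_act = 0.01), 100)
  expect_equal(activation_rate(0, 1, tau_deact = 0.04), -25)
  expect_error(activation_rate(1.5, 0))
})

test_that("curve anchors hold", {
  expect_equal(active_force_length(1), 1)
  expect_equal(force_velocity(0), 1)
  expect_equal(force_velocity(-1), 0)   # v expressed as V/vmax
  expect_lte(max(force_velocity(seq(0, 5, by = 0.1))), 1.5)
  expect_equal(passive_force(0.9), 0)
  expect_equal(passive_force(1.0), 0)
  expect_true(all(diff(passive_force(seq(1.01, 1.6, by = 0.01))) > 0))
  expect_equal(tendon_force(0), 0)
  expect_equal(tendon_force(-0.01), 0)
  expect_gt(tendon_force(0.03), 0)
  # inverse of the force-velocity curve round-trips
  v <- seq(-0.99, 0.9, by = 0.05)
  expect_equal(force_velocity_inverse(force_velocity(v)), v,
               tolerance = 1e-10)
})

test_that("curves are C1 (no derivative jumps at the joins)", {
  fd_slope <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
  for (x0 in c(-1e-4, 1e-4)) {  # around v = 0 and strain = 0, L = 1
    expect_equal(fd_slope(force_velocity, 0 + x0),
                 fd_slope(force_velocity, 0 - x0), tolerance = 1e-3)
  }
  expect_lt(abs(fd_slope(passive_force, 1 + 1e-5) -
                fd_slope(passive_force, 1 - 1e-5)), 1e-3)
  expect_lt(abs(fd_slope(tendon_force, 1e-5) -
                fd_slope(tendon_force, -1e-5)), 1e-2)
})

test_that("mtu_step: isometric optimum and slack behavior", {
  par <- list(fmax = 1000, lopt = 0.1, lslack = 0.2, vmax = 10)
  # pick lmt so that at equilibrium L = 1 with a = 1:
  # tendon must carry ~f_max -> strain 0.045
  lmt <- par$lopt + par$lslack * 1.045
  st <- list(a = 1, lce = par$lopt)
  for (i in 1:4000) st$lce <- mtu_step(par, st, lmt, 1e-4)$lce
  out <- mtu_step(par, st, lmt, 1e-4)
  expect_equal(out$V, 0, tolerance = 1e-3)
  expect_equal(out$F, 1, tolerance = 0.08)  # active + small passive near 1
  # slack muscle, zero activation: no force
  st0 <- list(a = 0, lce = 0.9 * par$lopt)
  out0 <- mtu_step(par, st0, 0.9 * (par$lopt + par$lslack), 1e-4)
  expect_lt(out0$F, 1e-6)
})

test_that("rigid-tendon mode agrees with the closed form", {
  par <- list(fmax = 500, lopt = 0.08, lslack = 0.15, vmax = 10)
  for (lmt in c(0.20, 0.23, 0.26)) {
    for (a in c(0, 0.4, 1)) {
      out <- mtu_step(par, list(a = a, lce = 0.1), lmt, 1e-4, rigid = TRUE,
                      mtu_length_prev = lmt - 0.001 * 1e-4 * 0)
      L <- (lmt - par$lslack) / par$lopt
      expect_equal(out$F,
                   max(0, a * active_force_length(L) * force_velocity(0) +
                         passive_force(L)),
                   tolerance = 1e-9)
    }
  }
})

test_that("forces stay non-negative and activation bounded in rollouts", {
  par <- list(fmax = 1000, lopt = 0.1, lslack = 0.2, vmax = 10)
  set.seed(7)
  st <- list(a = 0.5, lce = par$lopt)
  a <- st$a
  for (i in 1:500) {
    u <- runif(1)
    a <- min(1, max(0, a + 1e-3 * activation_rate(u, a)))
    lmt <- 0.3 + 0.05 * sin(i / 30)
    out <- mtu_step(par, list(a = a, lce = st$lce), lmt, 1e-3)
    st$lce <- out$lce
    expect_gte(out$F, 0)
    expect_true(a >= 0 && a <= 1)
  }
})
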