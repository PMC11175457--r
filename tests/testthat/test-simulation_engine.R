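# Integrator correctness: energy, momentum, delays, termination rules.

test_that("passive pendulum conserves energy to < 1% over 5 s", {
  m <- default_model_cached()
  q0 <- c(0, 2, 0, 0, 0, 1.0, 0.3, 0, 0.4, 0.1, 0)
  res <- sitwalk:::cpp_simulate(m$engine, list(
    q0 = q0, dt = 2e-4, tmax = 5, lock_root = TRUE, contact_on = FALSE,
    muscles_on = FALSE, limits_on = FALSE, joint_damping_on = FALSE,
    fall_check = FALSE), NULL)
  tr <- res$trajectory[seq_len(res$n_rec), ]
  E0 <- total_energy(m, q0, rep(0, 11))
  n <- nrow(tr)
  Eend <- total_energy(m, tr[n, 2:12], tr[n, 13:23])
  expect_lt(abs(Eend - E0) / abs(E0), 0.01)
})

test_that("zero gravity, zero forces: uniform motion", {
  m <- ball_model()
  st <- list(q = c(0, 1, 0), qd = c(0.3, 0.2, 0.5), act = NULL, lce = NULL,
             time = 0)
  out <- forward_step(m, st, dt = 1e-3, n_steps = 1000,
                      gravity_on = FALSE, contact_on = FALSE)
  expect_equal(out$q, c(0 + 0.3, 1 + 0.2, 0 + 0.5), tolerance = 1e-9)
  expect_equal(out$qd, c(0.3, 0.2, 0.5), tolerance = 1e-12)
})

test_that("static standing supports the body weight within 2%", {
  m <- default_model_cached()
  res <- sitwalk:::cpp_simulate(m$engine, list(
    q0 = c(0, 0.9952, rep(0, 9)), dt = 2e-4, tmax = 2,
    hold_kp = 2000, hold_kd = 50, muscles_on = FALSE,
    fall_check = FALSE), NULL)
  tr <- res$trajectory[seq_len(res$n_rec), ]
  n <- nrow(tr)
  grf_y <- tr[n, 1 + 22 + 100 + 2] + tr[n, 1 + 22 + 100 + 4]
  expect_equal(grf_y, 75 * 9.81, tolerance = 0.02 * 75 * 9.81)
})

test_that("linear momentum balance holds during a rollout", {
  # sum of external forces ~ M * a_com (checked at 1% of body weight against
  # finite-difference COM acceleration)
  m <- default_model_cached()
  res <- sitwalk:::cpp_simulate(m$engine, list(
    q0 = c(0, 0.9952, rep(0, 9)), dt = 2e-4, tmax = 1.0,
    hold_kp = 2000, hold_kd = 50, muscles_on = FALSE,
    fall_check = FALSE), NULL)
  tr <- res$trajectory[seq_len(res$n_rec), ]
  tt <- tr[, 1]
  comy <- tr[, 1 + 22 + 100 + 6 + 2 + 2]
  n <- length(tt)
  acc <- (comy[3:n] - 2 * comy[2:(n - 1)] + comy[1:(n - 2)]) / diff(tt)[1]^2
  fy <- tr[, 1 + 22 + 100 + 2] + tr[, 1 + 22 + 100 + 4]   # vertical GRF
  resid <- 75 * acc - (fy[2:(n - 1)] - 75 * 9.81)
  # skip the initial settling transient
  expect_lt(max(abs(resid[80:(n - 2)])), 0.01 * 75 * 9.81)
})

test_that("delayed_value interpolates and holds at start", {
  buf <- delay_buffer(c("a", "b"))
  for (t in seq(0, 1, by = 0.01)) push_sample(buf, t, c(a = 5, b = t))
  expect_equal(delayed_value(buf, "a", 1, 0.3), 5)
  expect_equal(delayed_value(buf, "b", 1, 0.035), 0.965, tolerance = 1e-9)
  expect_equal(delayed_value(buf, "b", 0, 0.5), 0)   # hold-at-start
  expect_equal(delayed_value(buf, "b", 0.2, 0.5), 0)
  expect_error(delayed_value(buf, "zz", 1, 0.1), "unknown")
  # interpolation error on a smooth signal is O(dt^2)
  buf2 <- delay_buffer("s")
  for (t in seq(0, 1, by = 0.01)) push_sample(buf2, t, sin(2 * pi * t))
  err <- abs(delayed_value(buf2, "s", 0.8, 0.123) - sin(2 * pi * (0.8 - 0.123)))
  expect_lt(err, (2 * pi * 0.01)^2)
})

test_that("fall rule is the strict 0.6-ratio threshold", {
  expect_true(detect_fall(0.59, 1))
  expect_false(detect_fall(0.61, 1))
  expect_false(detect_fall(0.60, 1))  # boundary: strict inequality
  expect_error(detect_fall(0.5, 0))
})

test_that("simulate respects the time cap and labels phases", {
  m <- default_model_cached()
  sc <- load_scenario(default_scenario_file("normal"))
  sc$max_time <- 1
  cfg <- default_controller_config()
  cfg <- set_parameters(cfg, c(global.t1 = 0.3, global.t2 = 0.7))
  traj <- simulate_s2w(m, cfg, sc)
  expect_equal(attr(traj, "end_time"), 1, tolerance = 1e-6)
  expect_equal(unique(traj$phase[traj$time < 0.3]), 0)
  expect_equal(unique(traj$phase[traj$time >= 0.3 & traj$time < 0.7]), 1)
  expect_equal(unique(traj$phase[traj$time >= 0.7]), 2)
  # phase labels partition the rollout
  expect_true(all(traj$phase %in% 0:2))
})

test_that("rollouts are deterministic", {
  m <- default_model_cached()
  sc <- load_scenario(default_scenario_file("normal"))
  sc$max_time <- 0.5
  cfg <- default_controller_config()
  t1 <- simulate_s2w(m, cfg, sc)
  t2 <- simulate_s2w(m, cfg, sc)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("a destabilizing controller triggers the fall flag early", {
  m <- default_model_cached()
  sc <- load_scenario(default_scenario_file("normal"))
  cfg <- default_controller_config()
  v <- cfg$params$value; v[] <- 0; names(v) <- cfg$params$name
  # yank the model down/forward: strong hip flexor drive
  v[grep("p1\\..\\.(iliac|psoas|rfem)\\.c0", names(v))] <- 1
  v["global.t1"] <- 6; v["global.t2"] <- 8
  cfg <- set_parameters(cfg, v)
  traj <- simulate_s2w(m, cfg, sc)
  expect_true(attr(traj, "fell"))
  expect_lt(attr(traj, "end_time"), 12)
})
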