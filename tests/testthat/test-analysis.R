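# Post-processing: trunk angle, joint loads, condition deltas, round-trips.

test_that("peak trunk angle from synthetic pitch channels", {
  tt <- seq(0, 2, by = 0.01)
  deg <- pi / 180
  # torso vertical throughout
  traj <- make_traj(tt)
  expect_equal(peak_trunk_angle(traj, "all"), 0)
  # constant 30 deg forward pitch via the lumbar joint (forward = negative CCW)
  traj2 <- make_traj(tt, q_lumbar = rep(-30 * deg, length(tt)))
  expect_equal(peak_trunk_angle(traj2, "all"), 30, tolerance = 1e-9)
  # sinusoidal pitch of amplitude A: peak = A
  A <- 42
  traj3 <- make_traj(tt, q_lumbar = -A * deg * sin(pi * tt / 2))
  expect_equal(peak_trunk_angle(traj3, "all"), A, tolerance = 0.1)
  # pelvis anterior tilt (positive) also pitches the trunk forward
  traj4 <- make_traj(tt, q_pelvis_tilt = rep(20 * deg, length(tt)))
  expect_equal(peak_trunk_angle(traj4, "all"), 20, tolerance = 1e-9)
  # phase filtering
  traj5 <- make_traj(tt, q_lumbar = ifelse(tt < 1, -10 * deg, -40 * deg),
                     phase = ifelse(tt < 1, 0, 2))
  expect_equal(peak_trunk_angle(traj5, "P1"), 10, tolerance = 1e-6)
  expect_equal(peak_trunk_angle(traj5, "GAIT"), 40, tolerance = 1e-6)
})

test_that("static joint reaction load matches the statics oracle", {
  m <- default_model_cached()
  # static standing at q = 0: hip load ~ half the superincumbent weight
  tt <- seq(0, 1, by = 0.01)
  n <- length(tt)
  traj <- make_traj(tt, q_pelvis_ty = rep(0.995, n),
                    grf_r_y = rep(75 * 9.81 / 2, n),
                    grf_l_y = rep(75 * 9.81 / 2, n))
  jr <- joint_reaction_load(traj, m, "hip_r")
  # distal subsystem = one leg (15 kg): F = m a - m g - GRF
  # static: |0 - (-15 g) - 368| = |147 - 368| ~ 221 N
  leg_w <- (10.5 + 3.5 + 1.0) * 9.81
  expect_equal(stats::median(jr$force), abs(leg_w - 75 * 9.81 / 2),
               tolerance = 1)
  # zero gravity, static, no muscle force, no contact: zero load
  m0 <- m; m0$gravity <- 0
  traj0 <- make_traj(tt, q_pelvis_ty = rep(0.995, n))
  jr0 <- joint_reaction_load(traj0, m0, "knee_r")
  expect_lt(max(jr0$force), 1e-6)
})

test_that("muscle tension adds to the transmitted joint load", {
  m <- default_model_cached()
  tt <- seq(0, 0.5, by = 0.01)
  n <- length(tt)
  base <- make_traj(tt, q_pelvis_ty = rep(0.995, n))
  with_mus <- make_traj(tt, q_pelvis_ty = rep(0.995, n),
                        F_vas_r = rep(0.2, n))   # single-joint knee muscle
  j0 <- joint_reaction_load(base, m, "knee_r")
  j1 <- joint_reaction_load(with_mus, m, "knee_r")
  tension <- 0.2 * m$muscles$fmax[match("vas_r", m$muscles$name)]
  inc <- stats::median(j1$force) - stats::median(j0$force)
  expect_equal(inc, tension, tolerance = 0.25 * tension)
})

test_that("condition comparison computes percent deltas", {
  base <- list(peak_load_knee_r = 100, peak_load_hip_r = 200, n_steps = 4)
  alt <- list(peak_load_knee_r = 115, peak_load_hip_r = 180, n_steps = 4)
  d <- compare_conditions(base, alt)
  expect_equal(d[["peak_load_knee_r"]], 15)
  expect_equal(d[["peak_load_hip_r"]], -10)
  expect_equal(unname(compare_conditions(base, base)),
               rep(0, length(compare_conditions(base, base))))
  # antisymmetry caveat: swapping changes the denominator
  d2 <- compare_conditions(alt, base)
  expect_equal(d2[["peak_load_knee_r"]], -100 * 15 / 115, tolerance = 1e-9)
})

test_that("result bundles round-trip through the CSV", {
  m <- default_model_cached()
  sc <- load_scenario(default_scenario_file("normal"))
  sc$max_time <- 0.8
  cfg <- default_controller_config()
  cfg <- set_parameters(cfg, c(global.t1 = 0.2, global.t2 = 0.6))
  traj <- simulate_s2w(m, cfg, sc)
  dir <- tempfile()
  files <- write_results(dir, traj, m, objective_report(traj, m, sc), cfg)
  expect_true(all(file.exists(files)))
  back <- read_trajectory(file.path(dir, "trajectory.csv"))
  s1 <- summarize_trajectory(traj, m)
  s2 <- summarize_trajectory(back, m)
  for (k in setdiff(names(s1), c("fell"))) {
    if (is.numeric(s1[[k]]) && is.finite(s1[[k]])) {
      expect_equal(s2[[k]], s1[[k]], tolerance = 1e-8, info = k)
    }
  }
  # empty trajectory refuses to serialize
  expect_error(write_results(tempfile(), traj[0, ], m), "empty")
})

test_that("scenario loading validates keys and postures", {
  f <- tempfile()
  writeLines(c("seat_height 0.35", "max_time 12"), f)
  sc <- load_scenario(f)
  expect_equal(sc$seat_height, 0.35)
  writeLines("not_a_key 1", f)
  expect_error(load_scenario(f), "not_a_key")
  # partial explicit posture: error names the missing coordinate
  writeLines(c("seat_height 0.44", "posture.hip_r 85"), f)
  sc2 <- load_scenario(f)
  expect_error(initial_posture(default_model_cached(), sc2), "pelvis_tx")
})

test_that("shipped scenario fixtures carry the stated seat heights", {
  expect_equal(load_scenario(default_scenario_file("normal"))$seat_height,
               0.44)
  expect_equal(load_scenario(default_scenario_file("low"))$seat_height,
               0.35)
  expect_equal(load_scenario(default_scenario_file("asymmetric"))$foot_offset_r,
               -0.10)
})
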