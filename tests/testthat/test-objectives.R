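# Movement objective: every measure is zero on its satisfying set, positive
# and monotone in violation, and the energy weights follow the stated
# 0.01 / 0.1 / 0.0003.

test_that("mimic measure: zero on the centerline, squared exceedance off it", {
  tt <- seq(0, 1.5, by = 0.01)
  corr <- make_corridor(c(0, 0.6), c(0.2, 1.0), halfwidth = 0.10,
                        duration = 1.5)
  cx <- approx(corr$times, corr$centerline[, 1], tt)$y
  cy <- approx(corr$times, corr$centerline[, 2], tt)$y
  on_line <- make_traj(tt, pelvis_com_x = cx, pelvis_com_y = cy)
  expect_equal(mimic_measure(on_line, corr), 0)
  # offset beyond the half-width by 0.05 m throughout
  off <- make_traj(tt, pelvis_com_x = cx, pelvis_com_y = cy + 0.15)
  expect_equal(mimic_measure(off, corr), 0.05^2, tolerance = 1e-9)
  # disabled corridor
  corr_inf <- make_corridor(c(0, 0.6), c(0.2, 1.0), halfwidth = Inf)
  expect_equal(mimic_measure(off, corr_inf), 0)
  # monotone in the violation
  off2 <- make_traj(tt, pelvis_com_x = cx, pelvis_com_y = cy + 0.25)
  expect_gt(mimic_measure(off2, corr), mimic_measure(off, corr))
})

test_that("step detection finds heel strikes after unloaded intervals", {
  tt <- seq(0, 4.5, by = 0.01)
  f <- ifelse(tt %% 1 < 0.6, 100, 0)   # loaded 0.6 s, unloaded 0.4 s
  traj <- make_traj(tt, heel_r_fy = f, T2 = 0.5)
  st <- detect_steps(traj, t_start = 0.5)
  expect_equal(st$time, c(1, 2, 3, 4), tolerance = 0.02)
  expect_true(all(st$leg == "r"))
  # too-short unloading is ignored
  f2 <- ifelse(tt %% 1 < 0.97 | tt %% 1 > 0.995, 100, 0)
  traj2 <- make_traj(tt, heel_r_fy = f2, T2 = 0.5)
  expect_equal(nrow(detect_steps(traj2, t_start = 0.5)), 0)
})

test_that("gait velocity measure penalizes the shortfall", {
  tt <- seq(0, 10, by = 0.01)
  mk <- function(v) make_traj(tt, pelvis_com_x = v * tt, T2 = 1)
  expect_equal(gait_velocity_measure(mk(1.0), 0.8)$penalty, 0)
  expect_equal(gait_velocity_measure(mk(0.8), 0.8)$penalty, 0,
               tolerance = 1e-9)
  expect_equal(gait_velocity_measure(mk(0.5), 0.8)$penalty, 0.3,
               tolerance = 1e-9)
  # velocity is evaluated from the end of the third step when steps exist
  f <- ifelse(tt %% 1 < 0.6, 100, 0)
  traj <- make_traj(tt, heel_r_fy = f, T2 = 0.5,
                    pelvis_com_x = ifelse(tt < 4, 0, (tt - 4) * 1.0))
  st <- detect_steps(traj, t_start = 0.5)
  vm <- gait_velocity_measure(traj, 0.8, st)
  expect_equal(vm$v_bar, 1.0, tolerance = 0.02)
})

test_that("range measure integrates exceedance in deg s", {
  tt <- seq(0, 2, by = 0.01)
  deg <- pi / 180
  # lumbar constant -25 deg: inside [-50, 0]
  traj <- make_traj(tt, q_lumbar = rep(-25 * deg, length(tt)))
  expect_equal(range_measure(traj, "lumbar", c(-50, 0)), 0)
  # thorax at 20 deg for 1 s beyond the +15 bound: 5 deg s
  q <- ifelse(tt < 1, 20 * deg, 0)
  traj2 <- make_traj(tt, q_thoracic = q)
  expect_equal(range_measure(traj2, "thoracic", c(-15, 15)), 5,
               tolerance = 0.1)
  # touching the bound exactly is free
  traj3 <- make_traj(tt, q_pelvis_tilt = rep(-50 * deg, length(tt)))
  expect_equal(range_measure(traj3, "pelvis_tilt", c(-50, 30)), 0)
})

test_that("knee limit measure integrates limit torque beyond threshold", {
  m <- default_model_cached()
  tt <- seq(0, 1, by = 0.01)
  traj0 <- make_traj(tt, q_knee_r = rep(0.5, length(tt)))
  expect_equal(knee_limit_measure(traj0, m), 0)
  # 0.1 rad beyond full extension: |tau| = 50 N m for 1 s
  traj1 <- make_traj(tt, q_knee_r = rep(-0.1, length(tt)))
  expect_equal(knee_limit_measure(traj1, m), 50, tolerance = 0.5)
})

test_that("head acceleration measure thresholds at 1 m/s^2", {
  tt <- seq(0, 2, by = 0.01)
  # quadratic head path: constant acceleration a
  mk <- function(a) make_traj(tt, head_x = 0.5 * a * tt^2, head_y = 1.7)
  expect_equal(head_acceleration_measure(mk(0.5)), 0)
  expect_equal(head_acceleration_measure(mk(1.0)), 0, tolerance = 1e-6)
  expect_equal(head_acceleration_measure(mk(2.0)), 1 * 2, tolerance = 0.05)
})

test_that("energy objective arithmetic uses the stated weights", {
  # weight arithmetic to machine precision
  rep <- list(mimic = 0, velocity = 0, range = c(a = 0), knee_limit = 0,
              head_acc = 0, J_mb = 100, J_act = 10, J_T = 1000,
              J_total = 0.01 * 100 + 0.1 * 10 + 3e-4 * 1000,
              fall_penalty = 0)
  expect_identical(rep$J_total, 1 + 1 + 0.3)
  expect_equal(total_objective(rep), 2.3)
  # one muscle at a = 1 contributes exactly 1 to J_act
  m <- default_model_cached()
  tt <- seq(0, 3, by = 0.01)
  traj <- make_traj(tt, act_sol_r = rep(1, length(tt)))
  en <- energy_objective(traj, m, t_gait = NA)
  expect_equal(en$J_act, 1, tolerance = 1e-9)
  # zero activations and torques: J_act = J_T = 0
  traj0 <- make_traj(tt)
  en0 <- energy_objective(traj0, m, t_gait = NA)
  expect_equal(en0$J_act, 0)
  expect_equal(en0$J_T, 0)
  expect_gt(en0$J_mb, 0)   # basal rate remains
})

test_that("total objective adds the fall penalty on early termination", {
  tt <- seq(0, 2, by = 0.01)
  m <- default_model_cached()
  traj <- make_traj(tt, fell = TRUE, end_time = 2)
  rep <- objective_report(traj, m,
    corridor = make_corridor(c(0, 0.6), c(0, 1), halfwidth = Inf))
  expect_true(rep$fall)
  expect_equal(rep$fall_penalty, 1000 * (1 - 2 / 12))
  expect_gt(rep$total, rep$fall_penalty)
  # purity: identical trajectories give identical totals
  rep2 <- objective_report(traj, m,
    corridor = make_corridor(c(0, 0.6), c(0, 1), halfwidth = Inf))
  expect_identical(rep$total, rep2$total)
})

test_that("measures honor the printed thresholds", {
  sc <- sitwalk:::.scenario_defaults()
  expect_identical(sc$v_min, 0.8)
  expect_identical(sc$head_acc_threshold, 1)
  expect_identical(sc$max_time, 12)
  expect_identical(sc$fall_ratio, 0.6)
  expect_identical(sc$w_mb, 0.01)
  expect_identical(sc$w_act, 0.1)
  expect_identical(sc$w_T, 3e-4)
})
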