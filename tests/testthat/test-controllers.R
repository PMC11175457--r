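# Reflex law, vestibular PD, configuration bookkeeping, gait state machine.

test_that("reflex pathway law evaluates the delayed-feedback equation", {
  pw <- function(...) utils::modifyList(
    list(c0 = 0, kl = 0, kf = 0, kv = 0, l0 = 1, sign = 1), list(...))
  expect_equal(reflex_excitation(pw(c0 = 0.1), 1, 0, 0), 0.1)
  expect_equal(reflex_excitation(pw(kl = 0.5), 1.3, 0, 0), 0.15)
  expect_equal(reflex_excitation(pw(kf = 0.2), 1, 0.5, 0), 0.10)
  expect_equal(reflex_excitation(pw(kv = 0.4, sign = -1), 1, 0, 0.5), -0.2)
})

test_that("vestibular PD law and sign routing", {
  p <- list(kp = 2, kv = 0, theta0 = 0.1)
  expect_equal(vestibular_excitation(p, 0.1, 0), 0)
  expect_equal(vestibular_excitation(p, 0.2, 0), 0.2)
  p2 <- list(kp = 1, kv = 0.5, theta0 = 0)
  expect_equal(vestibular_excitation(p2, 0, 0.4), 0.2)
})

test_that("default configuration encodes exactly 551 free parameters", {
  cfg <- default_controller_config()
  expect_equal(count_free_parameters(cfg), 551)
  expect_equal(length(encode_parameters(cfg)$values), 551)
})

test_that("symmetric sharing halves the per-leg muscle parameters", {
  sym <- default_controller_config("symmetric")
  per <- default_controller_config("per_leg")
  # per-leg-side muscle parameters: (551 - shared) / 2 remain free once
  shared <- sum(!grepl("\\.(r|l)\\.", per$params$name))
  side <- (551 - shared) / 2
  expect_equal(count_free_parameters(sym), shared + side)
  # mirrored values follow the right side
  sym2 <- set_parameters(sym, c(p1.r.gmax.c0 = 0.4))
  expect_equal(sym2$params$value[sym2$params$name == "p1.l.gmax.c0"], 0.4)
})

test_that("a reduced config counts its scalars by enumeration", {
  # one muscle, one phase, monosynaptic-only: C0, KL, KF, KV -> 4
  cfg <- default_controller_config()
  free <- cfg$params$free & grepl("^p1\\.r\\.sol\\.(c0|mono\\.)", cfg$params$name)
  expect_equal(sum(free), 4)
  # stand-up block: 2 phases x 2 legs x (10 C0 + 30 mono + 48 anta + 20 vest)
  standup <- grepl("^p[12]\\.(r|l)\\.", cfg$params$name)
  expect_equal(sum(standup), 4 * 108)
})

test_that("pathway table resolves latencies per the derivation", {
  m <- default_model_cached()
  cfg <- default_controller_config()
  tb <- build_pathway_table(cfg, m)
  expect_true(all(tb[tb[, "delay_ms"] > 0, "delay_ms"] %% 5 == 0))
  expect_true(all(tb[, "delay_ms"] <= 55))
  # mono rows for SOL carry 35 ms; vestibular GMAX rows carry 40 ms
  sol_r <- match("sol_r", m$muscles$name) - 1
  mono_sol <- tb[tb[, "target"] == sol_r & tb[, "type"] == 2 &
                   tb[, "src"] == sol_r & tb[, "phase"] == 0, "delay_ms"]
  expect_true(all(mono_sol == 35))
  gmax_r <- match("gmax_r", m$muscles$name) - 1
  vest_gmax <- tb[tb[, "target"] == gmax_r & tb[, "type"] == 4, "delay_ms"]
  expect_true(all(vest_gmax == 40))
  # monosynaptic length feedback is excitatory; antagonistic inhibitory
  ham_r <- match("ham_r", m$muscles$name) - 1
  rfem_r <- match("rfem_r", m$muscles$name) - 1
  mono_l <- tb[tb[, "target"] == ham_r & tb[, "type"] == 1 &
                 tb[, "src"] == ham_r, "sign"]
  anta_l <- tb[tb[, "target"] == ham_r & tb[, "type"] == 1 &
                 tb[, "src"] == rfem_r, "sign"]
  expect_true(all(mono_l == 1))
  expect_true(all(anta_l == -1))
})

test_that("starred gait pathways share one gain across states", {
  m <- default_model_cached()
  cfg <- default_controller_config()
  tb <- build_pathway_table(cfg, m)
  sol_r <- match("sol_r", m$muscles$name) - 1
  # SOL F+ appears once with a stance|lift-off mask, not per-state rows
  rows <- tb[tb[, "phase"] == 2 & tb[, "target"] == sol_r &
               tb[, "type"] == 2 & tb[, "src"] == sol_r, , drop = FALSE]
  expect_equal(nrow(rows), 1)
  expect_equal(unname(rows[1, "mask"]), 3)
  # TA length feedback is state-invariant (mask = all states)
  ta_r <- match("ta_r", m$muscles$name) - 1
  ta_rows <- tb[tb[, "phase"] == 2 & tb[, "target"] == ta_r &
                  tb[, "type"] == 1, , drop = FALSE]
  expect_equal(unname(ta_rows[1, "mask"]), 7)
})

test_that("controller step: phase schedule, summation, clamping, limits", {
  m <- default_model_cached()
  cfg <- default_controller_config()
  v <- cfg$params$value; v[] <- 0; names(v) <- cfg$params$name
  v[grep("^p1\\..\\..*\\.c0$", names(v))] <- 0.3
  v[grep("^p2\\..\\..*\\.c0$", names(v))] <- 0.7
  v["p1.lumbar.kp"] <- 1e6   # force saturation
  v["global.t1"] <- 1; v["global.t2"] <- 2
  cfg <- set_parameters(cfg, v)
  tb <- build_pathway_table(cfg, m)
  sig <- list(L = rep(1, 20), F = rep(0, 20), V = rep(0, 20),
              theta = 0, thetadot = 0, q = rep(1.5, 11), qd = rep(0, 11))
  s1 <- controller_step_r(tb, 0.5, sig)
  expect_equal(s1$excitation, rep(0.3, 20))
  expect_equal(s1$trunk_torque[1], -1000)   # saturated at the actuator limit
  s2 <- controller_step_r(tb, 1.5, sig)
  expect_equal(s2$excitation, rep(0.7, 20))
  s3 <- controller_step_r(tb, 5, sig)       # gait phase: constants are off
  expect_true(all(s3$excitation >= 0 & s3$excitation <= 1))
  # negative totals clamp to zero
  v2 <- v; v2[grep("^p1\\..\\..*\\.c0$", names(v2))] <- 0
  v2["p1.r.sol.anta_ta.kf"] <- 5
  cfg2 <- set_parameters(cfg, v2)
  tb2 <- build_pathway_table(cfg2, m)
  sig$F <- rep(0.5, 20)
  s4 <- controller_step_r(tb2, 0.5, sig)
  expect_equal(s4$excitation[match("sol_r", m$muscles$name)], 0)
})

test_that("gait state machine follows load with hysteresis", {
  # direct rule evaluation
  expect_equal(gait_state_update("stance", 0.5, 0.5, 0.1, t = 1)$state,
               "stance")
  expect_equal(gait_state_update("stance", 0.05, 0.5, 0.1, t = 1)$state,
               "liftoff")
  expect_equal(gait_state_update("liftoff", 0.001, 0.5, 0.1, t = 1)$state,
               "swing")
  expect_equal(gait_state_update("swing", 0.3, 0.5, 0.1, t = 1)$state,
               "stance")
  # dwell time suppresses chatter
  expect_equal(gait_state_update("stance", 0.05, 0.5, 0.1, t = 1,
                                 since = 0.995)$state, "stance")
})

test_that("state machine tracks a periodic load with the load's period", {
  period <- 1.2; thr <- 0.1; dt <- 0.002
  tt <- seq(0, 6, by = dt)
  load <- pmax(0, sin(2 * pi * tt / period)) * 0.8
  contra <- pmax(0, sin(2 * pi * tt / period + pi)) * 0.8
  st <- "stance"; since <- -Inf
  states <- character(length(tt))
  for (i in seq_along(tt)) {
    up <- gait_state_update(st, load[i], contra[i], thr, tt[i], since)
    st <- up$state; since <- up$since
    states[i] <- st
  }
  # onsets of stance recur with the load period
  onsets <- tt[which(states == "stance" & c("x", head(states, -1)) != "stance")]
  expect_gte(length(onsets), 3)
  expect_equal(diff(onsets), rep(period, length(onsets) - 1),
               tolerance = 0.05)
  # no chatter: each cycle has at most 3 state changes
  changes <- sum(states[-1] != head(states, -1))
  expect_lte(changes, 3 * 6 / period + 2)
})

test_that("parameter files round-trip losslessly", {
  cfg <- default_controller_config()
  set.seed(3)
  pv <- encode_parameters(cfg)
  vals <- pv$min + runif(551) * (pv$max - pv$min)
  cfg2 <- decode_parameters(vals, cfg)
  f <- tempfile(fileext = ".par")
  write_par_file(cfg2, f)
  cfg3 <- read_par_file(f, default_controller_config())
  expect_equal(cfg3$params$value, cfg2$params$value, tolerance = 1e-15)
  # encode/decode round-trip on the default config
  rt <- decode_parameters(encode_parameters(cfg)$values, cfg)
  expect_equal(rt$params$value, cfg$params$value)
  # out-of-bounds values clip to the bounds
  c4 <- decode_parameters(rep(1e9, 551), cfg)
  expect_true(all(c4$params$value <= c4$params$max + 1e-12))
})

test_that("transition times order and count transitions", {
  cfg <- default_controller_config()
  cfg <- set_parameters(cfg, c(global.t1 = 0.8, global.t2 = 2.5))
  tb <- build_pathway_table(cfg, default_model_cached())
  expect_lt(attr(tb, "T1"), attr(tb, "T2"))
  # exactly two transitions in [0, 12]
  phases <- vapply(seq(0, 12, by = 0.01), function(t)
    if (t < 0.8) 0 else if (t < 2.5) 1 else 2, numeric(1))
  expect_equal(sum(diff(phases) != 0), 2)
})
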