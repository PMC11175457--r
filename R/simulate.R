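# Forward simulation: rollout driver, single-step surface, delay buffers,
# fall rule, trajectory container.

.traj_colnames <- function(model) {
  co <- model$coords
  mu <- model$muscles$name
  c("time",
    paste0("q_", co), paste0("qd_", co),
    paste0("act_", mu), paste0("exc_", mu),
    paste0("L_", mu), paste0("V_", mu), paste0("F_", mu),
    "grf_r_x", "grf_r_y", "grf_l_x", "grf_l_y",
    "seat_x", "seat_y", "pelvis_com_x", "pelvis_com_y",
    "com_x", "com_y", "head_x", "head_y", "heel_r_fy", "heel_l_fy",
    "tau_lumbar", "tau_thoracic", "phase", "state_r", "state_l")
}

.head_point <- function(model) {
  ti <- match("torso", model$body_names)
  list(body = ti - 1L, local = c(0, model$segments$length[ti]))
}

#' Simulate a sit-to-walk rollout
#'
#' Runs the fixed-step forward simulation from the scenario's initial
#' posture (zero velocities) under the given controller until the maximum
#' simulation time (default 12 s) is reached or the model falls (whole-body
#' COM height below 0.6 x its initial value).  The trajectory is sampled at
#' 100 Hz and labeled with the controller phases P1/P2/GAIT.
#'
#' @param model An `s2w_model`.
#' @param controller An `s2w_controller`, a pathway table from
#'   [build_pathway_table()], or NULL (zero excitation everywhere).
#' @param scenario An `s2w_scenario` (see [load_scenario()]), or NULL for
#'   the normal-seat defaults.
#' @param excitation Optional constant excitation vector (used when
#'   `controller` is NULL).
#' @return An `s2w_trajectory`: data.frame of sampled channels with
#'   attributes `fell`, `end_time`, `model_coords`, `T2`, `scenario`.
#' @export
simulate_s2w <- function(model, controller = NULL, scenario = NULL,
                         excitation = NULL) {
  if (is.null(scenario)) {
    scenario <- structure(.scenario_defaults(), class = "s2w_scenario")
  }
  tb <- NULL
  if (inherits(controller, "s2w_controller")) {
    tb <- build_pathway_table(controller, model)
  } else if (is.matrix(controller)) {
    tb <- controller
  }
  q0 <- posture_to_q(model, initial_posture(model, scenario))
  chair <- chair_placement(model, scenario)
  hp <- .head_point(model)
  params <- list(
    q0 = q0, dt = scenario$dt, tmax = scenario$max_time,
    record_dt = 0.01, chair_on = TRUE,
    seat_x = chair$seat_x, seat_top = chair$seat_top,
    fall_ratio = scenario$fall_ratio,
    trunk_torque_limit = scenario$trunk_torque_limit,
    head_body = hp$body, head_local = hp$local)
  if (!is.null(tb)) {
    params$T1 <- attr(tb, "T1")
    params$T2 <- attr(tb, "T2")
    params$stance_threshold <- attr(tb, "stance_threshold")
  }
  if (!is.null(excitation)) params$excitation <- excitation
  res <- cpp_simulate(model$engine, params,
                      if (is.null(tb)) NULL else unclass(tb))
  tr <- as.data.frame(res$trajectory[seq_len(res$n_rec), , drop = FALSE])
  names(tr) <- .traj_colnames(model)
  structure(tr, class = c("s2w_trajectory", "data.frame"),
            fell = res$fell, end_time = res$end_time,
            com_y0 = res$com_y0, model_coords = model$coords,
            T1 = if (is.null(tb)) NA_real_ else attr(tb, "T1"),
            T2 = if (is.null(tb)) NA_real_ else attr(tb, "T2"),
            scenario = scenario, final_state = res$state)
}

#' Advance the model one integration step
#'
#' Single fixed-step update under prescribed controls (no reflex
#' controller): rigid-body and muscle states advance under gravity, muscle
#' forces, contact, and joint-limit torques.
#'
#' @param model An `s2w_model`.
#' @param state List with `q`, `qd` (length-11), `act`, `lce` (length-20),
#'   `time`; NULL entries take defaults (zero velocity, baseline
#'   activation).
#' @param controls List with `excitation` (length-20 in \[0,1\]),
#'   `lumbar_torque`, `thoracic_torque` (N m).
#' @param dt Step size (s).
#' @param n_steps Number of steps to take.
#' @param ... Extra engine flags (e.g. `contact_on = FALSE`,
#'   `gravity_on = FALSE`, `lock_root = TRUE`).
#' @return Updated state list (plus `trajectory` attribute of the sampled
#'   interval).
#' @export
forward_step <- function(model, state, controls = list(), dt = 2e-4,
                         n_steps = 1L, ...) {
  stopifnot(dt > 0)
  extra <- list(...)
  tau_ext <- rep(0, model$dof_count)
  if (!is.null(controls$lumbar_torque)) {
    tau_ext[match("lumbar", model$coords)] <- controls$lumbar_torque
  }
  if (!is.null(controls$thoracic_torque)) {
    tau_ext[match("thoracic", model$coords)] <- controls$thoracic_torque
  }
  u <- controls$excitation
  if (!is.null(u) && any(u < 0 | u > 1)) {
    stop("excitations must be within [0, 1]", call. = FALSE)
  }
  params <- c(list(
    q0 = state$q, qd0 = state$qd, act0 = state$act, lce0 = state$lce,
    dt = dt, tmax = dt * n_steps, record_dt = dt * n_steps,
    excitation = u, tau_ext = tau_ext, fall_check = FALSE,
    t0 = if (is.null(state$time)) 0 else state$time), extra)
  res <- cpp_simulate(model$engine, params, NULL)
  out <- res$state
  out$time <- (if (is.null(state$time)) 0 else state$time) + dt * n_steps
  attr(out, "trajectory") <- res$trajectory[seq_len(res$n_rec), , drop = FALSE]
  out
}

#' Fall detection rule
#'
#' @param com_height Current whole-body COM height (m).
#' @param initial_com_height COM height at simulation start (m).
#' @param ratio Fall threshold ratio.
#' @return TRUE iff `com_height < ratio * initial_com_height` (strict).
#' @export
detect_fall <- function(com_height, initial_com_height, ratio = 0.6) {
  stopifnot(initial_com_height > 0)
  com_height < ratio * initial_com_height
}

# ---------------------------------------------------------------------------
# delayed-signal buffer (R surface; the engine keeps its own ring buffers)

#' Delayed-signal buffer
#'
#' Stores per-channel (time, value) samples and answers delayed queries by
#' linear interpolation; queries earlier than the first sample return the
#' value at t = 0 (hold-at-start rule).
#'
#' @param channels Character vector of channel names.
#' @return A `s2w_delay_buffer` environment.
#' @export
delay_buffer <- function(channels) {
  env <- new.env(parent = emptyenv())
  env$channels <- channels
  env$time <- numeric(0)
  env$values <- matrix(numeric(0), nrow = 0, ncol = length(channels),
                       dimnames = list(NULL, channels))
  class(env) <- "s2w_delay_buffer"
  env
}

#' @rdname delay_buffer
#' @param buffer A `s2w_delay_buffer`.
#' @param t Sample time (non-decreasing).
#' @param values Named (or ordered) channel values.
#' @export
push_sample <- function(buffer, t, values) {
  buffer$time <- c(buffer$time, t)
  buffer$values <- rbind(buffer$values, as.numeric(values))
  invisible(buffer)
}

#' Delayed channel value
#'
#' Linearly interpolated channel value at `t - delay`; for query times
#' before the stored history the initial value is returned.
#'
#' @param buffer A `s2w_delay_buffer`.
#' @param channel Channel name.
#' @param t Current time (s).
#' @param delay Delay (s).
#' @return Channel value at `t - delay`.
#' @export
delayed_value <- function(buffer, channel, t, delay) {
  ci <- match(channel, buffer$channels)
  if (is.na(ci)) stop("unknown channel: ", channel, call. = FALSE)
  tq <- t - delay
  if (length(buffer$time) == 1 || tq <= buffer$time[1]) {
    return(unname(buffer$values[1, ci]))
  }
  unname(stats::approx(buffer$time, buffer$values[, ci], xout = tq,
                       rule = 2)$y)
}
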