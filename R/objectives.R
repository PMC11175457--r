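# The optimization objective: mimic, gait-velocity, range, head-acceleration
# and energy measures, aggregated into the rollout score.
#
# Every measure is >= 0 and exactly 0 on its satisfying set; the energy
# terms are weighted as J_total = w_mb J_mb + w_act J_act + w_T J_T with the
# stated weights 0.01 / 0.1 / 0.0003, and become the sole non-zero
# contribution once all task measures are met.

#' Stand-up pelvis-COM corridor
#'
#' Synthetic substitute for a measured pelvis-COM trajectory: a quintic
#' (minimum-jerk) blend in x and y from the seated pelvis COM to a point
#' above the mid-ankle at standing pelvis height, with a half-width band.
#' Its purpose is a rough stand-up path for the optimizer to start from
#' without dictating a specific motion pattern.  Like the measured
#' reference it stands in for, the corridor is time-indexed: the reference
#' point advances over a fixed window (default 1.5 s, a typical unhurried
#' stand-up duration), so a model that simply remains seated accrues a
#' penalty once the reference has risen.
#'
#' @param start Seated pelvis COM (x, y).
#' @param target Standing pelvis COM (x, y).
#' @param halfwidth Corridor half-width (m).
#' @param duration Time window over which the reference rises (s).
#' @param n Number of polyline points.
#' @return List with `centerline` (n x 2 matrix), `times` (s), `halfwidth`.
#' @export
make_corridor <- function(start, target, halfwidth = 0.10, duration = 1.5,
                          n = 50) {
  s <- seq(0, 1, length.out = n)
  blend <- 10 * s^3 - 15 * s^4 + 6 * s^5
  list(centerline = cbind(start[1] + (target[1] - start[1]) * blend,
                          start[2] + (target[2] - start[2]) * blend),
       times = s * duration, halfwidth = halfwidth)
}

#' Default corridor for a model / scenario
#'
#' Start point: pelvis COM of the scenario's initial posture.  Target:
#' above the mid-ankle position at the standing pelvis height (computed
#' from the model's segment geometry).
#'
#' @param model An `s2w_model`.
#' @param scenario An `s2w_scenario`.
#' @return Corridor list (see [make_corridor()]).
#' @export
default_corridor <- function(model, scenario) {
  q0 <- posture_to_q(model, initial_posture(model, scenario))
  bp <- cpp_body_poses(model$engine, q0)
  pi_ <- match("pelvis", model$body_names)
  th <- bp[pi_, 3]
  start <- c(bp[pi_, 1] + cos(th) * model$segments$com_x[pi_] -
               sin(th) * model$segments$com_y[pi_],
             bp[pi_, 2] + sin(th) * model$segments$com_x[pi_] +
               cos(th) * model$segments$com_y[pi_])
  feet <- match(c("foot_r", "foot_l"), model$body_names)
  ankle_x <- mean(bp[feet, 1])
  ankle_h <- bp[feet[1], 2]
  l_femur <- abs(model$joint_y[match("tibia_r", model$body_names)])
  l_tibia <- abs(model$joint_y[match("foot_r", model$body_names)])
  hip_dy <- model$joint_y[match("femur_r", model$body_names)]
  stand_y <- ankle_h + l_tibia + l_femur - hip_dy + model$segments$com_y[pi_]
  make_corridor(start, c(ankle_x, stand_y),
                halfwidth = scenario$corridor_halfwidth)
}

.dist_to_polyline <- function(px, py, line) {
  n <- nrow(line)
  a <- line[-n, , drop = FALSE]
  b <- line[-1, , drop = FALSE]
  abx <- b[, 1] - a[, 1]; aby <- b[, 2] - a[, 2]
  len2 <- abx^2 + aby^2 + 1e-12
  vapply(seq_along(px), function(i) {
    t <- clamp(((px[i] - a[, 1]) * abx + (py[i] - a[, 2]) * aby) / len2, 0, 1)
    dx <- a[, 1] + t * abx - px[i]
    dy <- a[, 2] + t * aby - py[i]
    sqrt(min(dx^2 + dy^2))
  }, numeric(1))
}

#' Stand-up mimic measure
#'
#' Mean squared exceedance of the pelvis COM outside the corridor band;
#' exactly zero when the trajectory stays inside everywhere.  With a
#' time-indexed corridor (the default) the deviation at each sample is
#' measured against the reference point at that time over the corridor
#' window; a corridor without `times` is treated as a purely spatial band.
#'
#' @param trajectory An `s2w_trajectory`.
#' @param corridor Corridor list ([make_corridor()]); an infinite
#'   half-width disables the measure.
#' @param t_end End of the evaluated interval (s); defaults to the
#'   corridor window (time-indexed) or the P2-to-gait transition (spatial).
#' @return Penalty (m^2).
#' @export
mimic_measure <- function(trajectory, corridor, t_end = NULL) {
  if (!is.finite(corridor$halfwidth)) return(0)
  if (!is.null(corridor$times)) {
    if (is.null(t_end)) t_end <- max(corridor$times)
    sel <- trajectory$time <= t_end
    if (!any(sel)) return(0)
    tt <- trajectory$time[sel]
    cx <- stats::approx(corridor$times, corridor$centerline[, 1], xout = tt,
                        rule = 2)$y
    cy <- stats::approx(corridor$times, corridor$centerline[, 2], xout = tt,
                        rule = 2)$y
    d <- sqrt((trajectory$pelvis_com_x[sel] - cx)^2 +
                (trajectory$pelvis_com_y[sel] - cy)^2)
    return(mean(pmax(0, d - corridor$halfwidth)^2))
  }
  if (is.null(t_end)) t_end <- attr(trajectory, "T2")
  if (is.null(t_end) || is.na(t_end)) t_end <- max(trajectory$time)
  sel <- trajectory$time <= t_end
  if (!any(sel)) return(0)
  d <- .dist_to_polyline(trajectory$pelvis_com_x[sel],
                         trajectory$pelvis_com_y[sel],
                         corridor$centerline)
  mean(pmax(0, d - corridor$halfwidth)^2)
}

#' Detect steps from heel-strike events
#'
#' A step begins when a heel-sphere vertical force rises through 30 N after
#' an unloaded interval of at least 50 ms.  Only events after `t_start`
#' (the gait transition) are reported.
#'
#' @param trajectory An `s2w_trajectory`.
#' @param t_start Earliest time to consider (s).
#' @param force_threshold Strike threshold (N).
#' @param unloaded_min Minimum preceding unloaded interval (s).
#' @return data.frame with columns `time`, `leg` ("r"/"l"), sorted by time.
#' @export
detect_steps <- function(trajectory, t_start = attr(trajectory, "T2"),
                         force_threshold = 30, unloaded_min = 0.050) {
  if (is.na(t_start)) t_start <- 0
  out <- list()
  for (leg in c("r", "l")) {
    f <- trajectory[[paste0("heel_", leg, "_fy")]]
    tt <- trajectory$time
    loaded <- f >= force_threshold
    unload_start <- NA_real_
    in_unload <- FALSE
    for (i in seq_along(f)) {
      if (!loaded[i]) {
        if (!in_unload) { in_unload <- TRUE; unload_start <- tt[i] }
      } else {
        if (in_unload && !is.na(unload_start) &&
            tt[i] - unload_start >= unloaded_min && tt[i] >= t_start) {
          out[[length(out) + 1]] <- data.frame(time = tt[i], leg = leg)
        }
        in_unload <- FALSE
      }
    }
  }
  if (!length(out)) {
    return(data.frame(time = numeric(0), leg = character(0)))
  }
  ev <- do.call(rbind, out)
  ev[order(ev$time), , drop = FALSE]
}

#' Gait velocity measure
#'
#' Average forward pelvis velocity from the end of the third step to the
#' end of the trajectory, penalized by its shortfall against `v_min`
#' (`max(0, v_min - vbar)`).  With fewer than four steps the full
#' post-stand-up interval is used.
#'
#' @param trajectory An `s2w_trajectory`.
#' @param v_min Minimum gait velocity (m/s).
#' @param steps Step events from [detect_steps()].
#' @return List with `penalty` and `v_bar`.
#' @export
gait_velocity_measure <- function(trajectory, v_min = 0.8,
                                  steps = detect_steps(trajectory)) {
  t2 <- attr(trajectory, "T2")
  t_from <- if (nrow(steps) >= 4) steps$time[4]
            else if (is.na(t2)) 0 else min(t2, max(trajectory$time))
  sel <- trajectory$time >= t_from
  tt <- trajectory$time[sel]
  xx <- trajectory$pelvis_com_x[sel]
  if (length(tt) < 2 || diff(range(tt)) < 1e-9) {
    return(list(penalty = v_min, v_bar = 0))
  }
  v_bar <- (xx[length(xx)] - xx[1]) / (tt[length(tt)] - tt[1])
  list(penalty = max(0, v_min - v_bar), v_bar = v_bar)
}

#' Joint range measure
#'
#' Time-integrated absolute exceedance of a coordinate beyond its bounds
#' (deg s); zero within bounds.
#'
#' @param trajectory An `s2w_trajectory`.
#' @param coordinate Coordinate name (e.g. `"lumbar"`).
#' @param bounds Numeric (lo, hi) in degrees.
#' @return Penalty (deg s).
#' @export
range_measure <- function(trajectory, coordinate, bounds) {
  stopifnot(bounds[1] <= bounds[2])
  q <- trajectory[[paste0("q_", coordinate)]] * 180 / pi
  exceed <- pmax(0, q - bounds[2]) + pmax(0, bounds[1] - q)
  dt <- diff(trajectory$time)
  sum(0.5 * (exceed[-1] + exceed[-length(exceed)]) * dt)
}

#' Knee limit-force range measure
#'
#' Integrates the knee joint-limit torque magnitude above a threshold
#' (N m s): the knee has no kinematic bound in the objective, but excessive
#' ligament (limit) loading is penalized.
#'
#' @param trajectory An `s2w_trajectory`.
#' @param model An `s2w_model`.
#' @param threshold Limit-torque threshold (N m).
#' @return Penalty (N m s), summed over both knees.
#' @export
knee_limit_measure <- function(trajectory, model, threshold = 0) {
  total <- 0
  for (kn in c("knee_r", "knee_l")) {
    tau <- joint_limit_torque(model, kn,
                              trajectory[[paste0("q_", kn)]],
                              trajectory[[paste0("qd_", kn)]])
    exceed <- pmax(0, abs(tau) - threshold)
    dt <- diff(trajectory$time)
    total <- total + sum(0.5 * (exceed[-1] + exceed[-length(exceed)]) * dt)
  }
  total
}

#' Head acceleration of a trajectory
#'
#' Finite-difference acceleration magnitude of the head point (top of the
#' torso) at the trajectory sampling rate.
#'
#' @param trajectory An `s2w_trajectory`.
#' @return Vector of |a_head| (m/s^2), same length as the trajectory.
#' @export
head_acceleration <- function(trajectory) {
  tt <- trajectory$time
  n <- length(tt)
  if (n < 3) return(rep(0, n))
  fd <- function(x) {
    v <- c(diff(x[1:2]) / diff(tt[1:2]),
           (x[-(1:2)] - x[1:(n - 2)]) / (tt[-(1:2)] - tt[1:(n - 2)]),
           diff(x[(n - 1):n]) / diff(tt[(n - 1):n]))
    c(diff(v[1:2]) / diff(tt[1:2]),
      (v[-(1:2)] - v[1:(n - 2)]) / (tt[-(1:2)] - tt[1:(n - 2)]),
      diff(v[(n - 1):n]) / diff(tt[(n - 1):n]))
  }
  sqrt(fd(trajectory$head_x)^2 + fd(trajectory$head_y)^2)
}

#' Head-acceleration measure
#'
#' Time-integrated exceedance of the head-point acceleration magnitude
#' above the threshold (default 1 m/s^2).
#'
#' @param trajectory An `s2w_trajectory`.
#' @param threshold Threshold (m/s^2).
#' @param acc Optional precomputed |a_head| channel.
#' @return Penalty (m/s).
#' @export
head_acceleration_measure <- function(trajectory, threshold = 1,
                                      acc = head_acceleration(trajectory)) {
  exceed <- pmax(0, acc - threshold)
  dt <- diff(trajectory$time)
  sum(0.5 * (exceed[-1] + exceed[-length(exceed)]) * dt)
}

# muscle-level metabolic rate (activation/maintenance + shortening heat +
# positive mechanical CE work + basal), a compact member of the standard
# muscle-energetics family; coefficients are documented fixture constants
.metabolic_constants <- function() {
  list(sigma = 0.25e6,   # specific tension, Pa
       rho = 1059.7,     # muscle density, kg/m^3
       act_rate = 40,    # W/kg, activation heat coefficient
       maint_rate = 74,  # W/kg, maintenance heat coefficient (x a x fl)
       shorten_coef = 0.25,  # dimensionless, x F x |v_ce| when shortening
       basal = 1.2)      # W/kg body mass
}

#' Metabolic rate channel of a trajectory
#'
#' @param trajectory An `s2w_trajectory`.
#' @param model An `s2w_model`.
#' @return Whole-body metabolic rate (W) per sample.
#' @export
metabolic_rate <- function(trajectory, model) {
  mc <- .metabolic_constants()
  mus <- model$muscles
  m_mus <- mus$fmax / mc$sigma * mc$rho * mus$lopt
  rate <- rep(mc$basal * model$total_mass, nrow(trajectory))
  for (i in seq_len(nrow(mus))) {
    nm <- mus$name[i]
    a <- trajectory[[paste0("act_", nm)]]
    L <- trajectory[[paste0("L_", nm)]]
    V <- trajectory[[paste0("V_", nm)]]     # lopt/s, lengthening positive
    F <- trajectory[[paste0("F_", nm)]]     # normalized
    fl <- active_force_length(L)
    v_ce <- V * mus$lopt[i]                 # m/s
    heat <- m_mus[i] * (mc$act_rate * a + mc$maint_rate * a * fl)
    shorten <- mc$shorten_coef * F * mus$fmax[i] * pmax(0, -v_ce)
    work <- F * mus$fmax[i] * pmax(0, -v_ce)
    rate <- rate + heat + shorten + work
  }
  rate
}

#' Energy objective
#'
#' `J_act`: summed time-average cubed activation.  `J_T`: summed
#' time-average squared lumbar/thoracic torque.  `J_mb`: metabolic rate
#' integral normalized per duration during stand-up and per distance
#' traveled during gait (gross cost of transport).
#' `J_total = w_mb J_mb + w_act J_act + w_T J_T`.
#'
#' @param trajectory An `s2w_trajectory`.
#' @param model An `s2w_model`.
#' @param w_mb,w_act,w_T Energy weights.
#' @param t_gait Gait transition time (s); defaults to the trajectory's T2.
#' @return List with `J_mb`, `J_act`, `J_T`, `J_total`.
#' @export
energy_objective <- function(trajectory, model, w_mb = 0.01, w_act = 0.1,
                             w_T = 3e-4, t_gait = attr(trajectory, "T2")) {
  tt <- trajectory$time
  dur <- max(tt) - min(tt)
  if (dur <= 0) return(list(J_mb = 0, J_act = 0, J_T = 0, J_total = 0))
  integ <- function(x, sel = TRUE) {
    x <- x * sel
    sum(0.5 * (x[-1] + x[-length(x)]) * diff(tt))
  }
  a3 <- rowSums(as.matrix(
    trajectory[, paste0("act_", model$muscles$name), drop = FALSE])^3)
  J_act <- integ(a3) / dur
  J_T <- integ(trajectory$tau_lumbar^2 + trajectory$tau_thoracic^2) / dur
  rate <- metabolic_rate(trajectory, model)
  if (is.na(t_gait) || t_gait >= max(tt)) {
    J_mb <- integ(rate) / dur
  } else {
    standup <- tt <= t_gait
    dist <- max(trajectory$pelvis_com_x[!standup]) -
            min(trajectory$pelvis_com_x[!standup])
    J_mb <- integ(rate, standup) / max(t_gait, 1e-6) +
            integ(rate, !standup) / max(dist, 0.1)
  }
  list(J_mb = J_mb, J_act = J_act, J_T = J_T,
       J_total = w_mb * J_mb + w_act * J_act + w_T * J_T)
}

#' Full objective report for a rollout
#'
#' Computes every measure and the weighted total, including the fall
#' penalty (`w_fall x` the unsimulated time fraction) when the rollout
#' terminated early.
#'
#' @param trajectory An `s2w_trajectory`.
#' @param model An `s2w_model`.
#' @param scenario An `s2w_scenario` (weights, thresholds); defaults to the
#'   trajectory's own.
#' @param corridor Optional corridor override.
#' @return An `s2w_objective_report` list.
#' @export
objective_report <- function(trajectory, model,
                             scenario = attr(trajectory, "scenario"),
                             corridor = NULL) {
  if (is.null(scenario)) {
    scenario <- structure(.scenario_defaults(), class = "s2w_scenario")
  }
  if (is.null(corridor)) corridor <- default_corridor(model, scenario)
  steps <- detect_steps(trajectory)
  vel <- gait_velocity_measure(trajectory, scenario$v_min, steps)
  ranges <- c(
    lumbar = range_measure(trajectory, "lumbar", c(-50, 0)),
    thoracic = range_measure(trajectory, "thoracic", c(-15, 15)),
    pelvis_tilt = range_measure(trajectory, "pelvis_tilt", c(-50, 30)),
    ankle_r = range_measure(trajectory, "ankle_r", c(-60, 60)),
    ankle_l = range_measure(trajectory, "ankle_l", c(-60, 60)))
  knee <- knee_limit_measure(trajectory, model,
                             scenario$knee_limit_threshold)
  mim <- mimic_measure(trajectory, corridor)
  head <- head_acceleration_measure(trajectory, scenario$head_acc_threshold)
  en <- energy_objective(trajectory, model, scenario$w_mb, scenario$w_act,
                         scenario$w_T)
  fell <- isTRUE(attr(trajectory, "fell"))
  end_time <- attr(trajectory, "end_time")
  if (is.null(end_time)) end_time <- max(trajectory$time)
  fall_pen <- if (fell) {
    scenario$w_fall * (1 - end_time / scenario$max_time)
  } else 0
  report <- list(
    mimic = mim, velocity = vel$penalty, v_bar = vel$v_bar,
    range = ranges, knee_limit = knee, head_acc = head,
    J_mb = en$J_mb, J_act = en$J_act, J_T = en$J_T, J_total = en$J_total,
    fall = fell, fall_penalty = fall_pen, end_time = end_time,
    n_steps = nrow(steps))
  report$total <- total_objective(report, scenario)
  class(report) <- "s2w_objective_report"
  report
}

#' Total objective from a report
#'
#' Weighted sum of all measures plus the fall penalty; equals `J_total`
#' when every task measure is zero and no fall occurred.
#'
#' @param report An `s2w_objective_report` (or compatible list).
#' @param scenario Scenario carrying the measure weights.
#' @return Scalar objective (minimized).
#' @export
total_objective <- function(report, scenario = NULL) {
  if (is.null(scenario)) {
    scenario <- structure(.scenario_defaults(), class = "s2w_scenario")
  }
  scenario$w_mimic * report$mimic +
    scenario$w_velocity * report$velocity +
    scenario$w_range * sum(report$range) +
    scenario$w_knee * report$knee_limit +
    scenario$w_headacc * report$head_acc +
    report$J_total +
    report$fall_penalty
}

#' @export
print.s2w_objective_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<objective report> total = %.4f\n",
    "  mimic %.5f | velocity %.3f (v=%.2f m/s) | range %.2f deg s | ",
    "knee %.2f | head %.3f\n",
    "  J_mb %.2f  J_act %.4f  J_T %.1f  J_total %.4f\n",
    "  fall %s (end %.2f s, %d steps)\n"),
    x$total, x$mimic, x$velocity, x$v_bar, sum(x$range), x$knee_limit,
    x$head_acc, x$J_mb, x$J_act, x$J_T, x$J_total,
    if (x$fall) "YES" else "no", x$end_time, x$n_steps))
  invisible(x)
}
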