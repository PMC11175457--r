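# Scenario configuration: seat height, initial posture, engine settings,
# measure configuration.  Scenario files are flat `key value` text.

.scenario_defaults <- function() {
  list(
    name = "scenario",
    seat_height = 0.44,          # m, chair top surface (0.35 = low seat)
    max_time = 12,               # s, simulation cap
    dt = 2e-4,                   # s, integration step
    foot_offset_r = 0,           # m, anterior-posterior shift of right foot
    foot_offset_l = 0,
    lumbar_angle = -5,           # deg, initial lumbar angle
    thoracic_angle = 0,          # deg
    pelvis_tilt = 0,             # deg, initial anterior tilt
    v_min = 0.8,                 # m/s, gait velocity target
    head_acc_threshold = 1,      # m/s^2
    fall_ratio = 0.6,            # fall when COM height < ratio * initial
    corridor_halfwidth = 0.10,   # m, stand-up pelvis-COM corridor
    w_mb = 0.01, w_act = 0.1, w_T = 3e-4,   # energy weights
    # task weights: chosen so that no single incidental violation (e.g. the
    # terminal collapse of a falling candidate) swamps the fall/velocity
    # staircase the optimizer climbs
    w_mimic = 1000, w_velocity = 100, w_range = 0.2,
    w_knee = 0.005, w_headacc = 0.2, w_fall = 1000,
    knee_limit_threshold = 0,    # N m, knee limit-torque penalty threshold
    trunk_torque_limit = 1000    # N m
  )
}

#' Load a scenario configuration
#'
#' Flat `key value` text; unknown keys are rejected, missing keys take
#' documented defaults.  Explicit initial postures may be given as
#' `posture.<coordinate> <value>` records (deg for angles, m for pelvis
#' translations); when any posture record is present, every model
#' coordinate must be listed.
#'
#' @param path Scenario file path.
#' @return An object of class `s2w_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  sc <- .scenario_defaults()
  posture <- c()
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (nchar(ln) == 0) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- tok[1]
    if (startsWith(key, "posture.")) {
      posture[sub("^posture\\.", "", key)] <- as.numeric(tok[2])
    } else if (key %in% names(sc)) {
      sc[[key]] <- if (key == "name") tok[2] else as.numeric(tok[2])
    } else {
      stop(sprintf("scenario file line %d: unknown key '%s'", i, key),
           call. = FALSE)
    }
  }
  if (length(posture)) sc$posture <- posture
  structure(sc, class = "s2w_scenario")
}

#' Shipped scenario fixtures
#' @param which `"normal"`, `"low"`, or `"asymmetric"`.
#' @return File path.
#' @export
default_scenario_file <- function(which = c("normal", "low", "asymmetric")) {
  which <- match.arg(which)
  system.file("extdata", paste0("scenario_", which, ".txt"),
              package = "sitwalk", mustWork = TRUE)
}

#' Seated initial posture
#'
#' Places the model seated on a chair of the given height: pelvis above the
#' chair (buttock sphere just touching the seat surface), feet flat on the
#' ground with the ankles at a configurable anterior-posterior offset, legs
#' solved by two-link inverse kinematics (about 85 deg hip and knee flexion
#' at the normal 0.44 m seat).  All velocities are zero.
#'
#' @param model An `s2w_model`.
#' @param seat_height Chair top surface height (m).
#' @param foot_offset_r,foot_offset_l Ankle shift along x relative to the
#'   default placement (m; negative = backwards).
#' @param lumbar_angle,thoracic_angle,pelvis_tilt Initial trunk angles (deg).
#' @return Named posture vector (class `s2w_posture`): angles in degrees,
#'   pelvis translations in metres, one entry per model coordinate.
#' @export
seated_posture <- function(model, seat_height = 0.44,
                           foot_offset_r = 0, foot_offset_l = 0,
                           lumbar_angle = -5, thoracic_angle = 0,
                           pelvis_tilt = 0) {
  e <- model$engine
  # geometry pulled from the model: buttock sphere offset, foot sphere drop
  bi <- which(e$sp_buttock == 1L)[1]
  foot_sp <- which(e$sp_buttock == 0L)
  ankle_h <- -(min(e$sp_y[foot_sp]) - max(e$sp_r[foot_sp]))  # ankle height
  l_femur <- abs(model$joint_y[match("tibia_r", model$body_names)])
  l_tibia <- abs(model$joint_y[match("foot_r", model$body_names)])
  hip_dy <- model$joint_y[match("femur_r", model$body_names)]

  pelvis_ty <- seat_height + e$sp_r[bi] - e$sp_y[bi] - 0.020
  hip <- c(0, pelvis_ty + hip_dy)
  leg_ik <- function(offset) {
    ankle <- c(0.38 + offset, ankle_h)
    d <- ankle - hip
    D <- min(sqrt(sum(d^2)), 0.999 * (l_femur + l_tibia))
    beta <- acos(clamp((l_femur^2 + l_tibia^2 - D^2) / (2 * l_femur * l_tibia),
                       -1, 1))
    alpha <- acos(clamp((l_femur^2 + D^2 - l_tibia^2) / (2 * l_femur * D),
                        -1, 1))
    phi <- atan2(d[1], -d[2])
    q_h <- phi + alpha          # hip flexion, rad
    q_k <- pi - beta            # knee flexion, rad
    q_a <- q_k - q_h            # dorsiflexion keeping the foot flat
    c(hip = q_h, knee = q_k, ankle = q_a) * 180 / pi
  }
  r <- leg_ik(foot_offset_r)
  l <- leg_ik(foot_offset_l)
  p <- c(pelvis_tx = 0, pelvis_ty = pelvis_ty, pelvis_tilt = pelvis_tilt,
         lumbar = lumbar_angle, thoracic = thoracic_angle,
         hip_r = r[["hip"]], knee_r = r[["knee"]], ankle_r = r[["ankle"]],
         hip_l = l[["hip"]], knee_l = l[["knee"]], ankle_l = l[["ankle"]])
  structure(p[model$coords], class = "s2w_posture", names = model$coords)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Initial posture for a scenario
#'
#' Explicit `posture.*` records take precedence (validated for
#' completeness); otherwise the seated posture is constructed from the
#' scenario's seat height and foot offsets.
#'
#' @param model An `s2w_model`.
#' @param scenario An `s2w_scenario`.
#' @return Posture vector (deg / m), ordered as `model$coords`.
#' @export
initial_posture <- function(model, scenario) {
  if (!is.null(scenario$posture)) {
    miss <- setdiff(model$coords, names(scenario$posture))
    if (length(miss)) {
      stop("scenario posture is missing coordinate(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    return(structure(scenario$posture[model$coords], class = "s2w_posture"))
  }
  seated_posture(model, scenario$seat_height,
                 scenario$foot_offset_r, scenario$foot_offset_l,
                 scenario$lumbar_angle, scenario$thoracic_angle,
                 scenario$pelvis_tilt)
}

#' Convert a posture (deg / m) to generalized coordinates (rad / m)
#' @param model An `s2w_model`.
#' @param posture Named posture vector.
#' @return Numeric vector ordered as `model$coords`.
#' @export
posture_to_q <- function(model, posture) {
  q <- as.numeric(posture[model$coords])
  ang <- !(model$coords %in% c("pelvis_tx", "pelvis_ty"))
  q[ang] <- q[ang] * pi / 180
  q
}

#' Chair placement for a scenario
#'
#' The chair box is fixed in the ground frame: top surface at the seat
#' height, centered under the buttock sphere of the initial posture.
#'
#' @param model An `s2w_model`.
#' @param scenario An `s2w_scenario`.
#' @return List with `seat_x` (box center x) and `seat_top` (m).
#' @export
chair_placement <- function(model, scenario) {
  p <- initial_posture(model, scenario)
  e <- model$engine
  bi <- which(e$sp_buttock == 1L)[1]
  tilt <- p[["pelvis_tilt"]] * pi / 180 * model$joint_sign[1]
  cx <- p[["pelvis_tx"]] + cos(tilt) * e$sp_x[bi] - sin(tilt) * e$sp_y[bi]
  list(seat_x = cx, seat_top = scenario$seat_height)
}
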