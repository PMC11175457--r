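# Post-processing: trunk angle, joint reaction loading, condition
# comparisons, result serialization.

#' Peak trunk angle
#'
#' Maximum forward inclination of the torso long axis from the global
#' vertical within a controller phase (degrees).  The torso world
#' orientation is reconstructed from the pelvis tilt and the lumbar and
#' thoracic angles.
#'
#' @param trajectory An `s2w_trajectory`.
#' @param phase `"P1"`, `"P2"`, `"GAIT"`, `"standup"` (P1+P2) or `"all"`.
#' @return Peak forward trunk angle (deg).
#' @export
peak_trunk_angle <- function(trajectory, phase = "standup") {
  sel <- switch(toupper(phase),
    P1 = trajectory$phase == 0,
    P2 = trajectory$phase == 1,
    GAIT = trajectory$phase == 2,
    STANDUP = trajectory$phase <= 1,
    ALL = rep(TRUE, nrow(trajectory)),
    stop("unknown phase: ", phase))
  if (!any(sel)) return(NA_real_)
  # torso CCW world angle = -pelvis_tilt + lumbar + thoracic;
  # forward lean (toward +x) is the negative CCW direction
  th <- -trajectory$q_pelvis_tilt[sel] + trajectory$q_lumbar[sel] +
    trajectory$q_thoracic[sel]
  max(-th) * 180 / pi
}

.subtree_bodies <- function(model, joint) {
  child <- model$joints$child[model$joints$name == joint]
  if (!length(child)) stop("unknown joint: ", joint, call. = FALSE)
  ci <- match(child, model$body_names)
  out <- ci
  repeat {
    grow <- which(model$parent %in% out & !(seq_along(model$parent) %in% out))
    if (!length(grow)) break
    out <- c(out, grow)
  }
  out
}

#' Joint reaction load
#'
#' Magnitude of the resultant intersegmental force transmitted at a pin
#' joint, including muscle-force contributions: for the subsystem distal to
#' the joint, `F = sum(m (a - g)) - F_contact - F_muscle`, where `F_muscle`
#' collects the forces that muscles crossing the joint apply to the distal
#' side (so muscle tension increases the transmitted load).  COM
#' accelerations are obtained by finite differencing the recorded
#' kinematics at the sampling rate.
#'
#' @param trajectory An `s2w_trajectory`.
#' @param model An `s2w_model`.
#' @param joint Pin joint name (`"hip_r"`, `"knee_l"`, ...).
#' @return List: `force` (N, per sample), `bw` (body-weight normalized),
#'   `time`.
#' @export
joint_reaction_load <- function(trajectory, model, joint) {
  sub <- .subtree_bodies(model, joint)
  nb <- length(model$body_names)
  ns <- nrow(trajectory)
  qcols <- paste0("q_", model$coords)
  segs <- model$segments
  g <- model$gravity

  # per-sample COM positions of the distal subsystem + world via points of
  # crossing muscles
  crossing <- character(0)
  for (mn in model$muscles$name) {
    vp <- model$viapoints[model$viapoints$muscle == mn, , drop = FALSE]
    bi <- match(vp$segment, model$body_names)
    inn <- bi %in% sub
    if (any(inn) && !all(inn)) crossing <- c(crossing, mn)
  }

  com <- array(NA_real_, c(ns, length(sub), 2))
  fmus <- matrix(0, ns, 2)
  for (i in seq_len(ns)) {
    q <- as.numeric(trajectory[i, qcols])
    bp <- cpp_body_poses(model$engine, q)
    th <- bp[sub, 3]
    com[i, , 1] <- bp[sub, 1] + cos(th) * segs$com_x[sub] -
      sin(th) * segs$com_y[sub]
    com[i, , 2] <- bp[sub, 2] + sin(th) * segs$com_x[sub] +
      cos(th) * segs$com_y[sub]
    for (mn in crossing) {
      Fn <- trajectory[[paste0("F_", mn)]][i]
      if (Fn <= 0) next
      Tn <- Fn * model$muscles$fmax[match(mn, model$muscles$name)]
      vp <- model$viapoints[model$viapoints$muscle == mn, , drop = FALSE]
      bi <- match(vp$segment, model$body_names)
      wp <- cbind(bp[bi, 1] + cos(bp[bi, 3]) * vp$x - sin(bp[bi, 3]) * vp$y,
                  bp[bi, 2] + sin(bp[bi, 3]) * vp$x + cos(bp[bi, 3]) * vp$y)
      inn <- bi %in% sub
      # crossing path segments pull the distal attachment toward the
      # proximal side
      for (k in seq_len(nrow(vp) - 1)) {
        if (inn[k] == inn[k + 1]) next
        u <- wp[k + 1, ] - wp[k, ]
        u <- u / max(sqrt(sum(u^2)), 1e-12)
        fmus[i, ] <- fmus[i, ] + if (inn[k]) Tn * u else -Tn * u
      }
    }
  }
  tt <- trajectory$time
  fd2 <- function(x) {  # second derivative by central differences
    n <- length(x)
    if (n < 3) return(rep(0, n))
    a <- rep(0, n)
    a[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) /
      ((tt[3:n] - tt[1:(n - 2)]) / 2)^2
    a[1] <- a[2]; a[n] <- a[n - 1]
    a
  }
  acc_x <- sapply(seq_along(sub), function(b) fd2(com[, b, 1]))
  acc_y <- sapply(seq_along(sub), function(b) fd2(com[, b, 2]))
  mass <- segs$mass[sub]
  inert_x <- acc_x %*% mass
  inert_y <- acc_y %*% mass + sum(mass) * g
  # external contact on the distal subsystem: the foot of that subtree
  fx <- rep(0, ns); fy <- rep(0, ns)
  for (leg in c("r", "l")) {
    foot <- match(paste0("foot_", leg), model$body_names)
    if (!is.na(foot) && foot %in% sub) {
      fx <- fx + trajectory[[paste0("grf_", leg, "_x")]]
      fy <- fy + trajectory[[paste0("grf_", leg, "_y")]]
    }
  }
  Fx <- inert_x - fx - fmus[, 1]
  Fy <- inert_y - fy - fmus[, 2]
  force <- sqrt(Fx^2 + Fy^2)
  list(force = force, bw = force / (model$total_mass * g), time = tt)
}

#' Trajectory summary
#'
#' Derived metrics recomputable from the trajectory alone: peak trunk
#' angle, per-joint peak reaction loads, step events, seat-off time, gait
#' velocity, displacement.
#'
#' @param trajectory An `s2w_trajectory`.
#' @param model An `s2w_model`.
#' @return Named list (class `s2w_summary`).
#' @export
summarize_trajectory <- function(trajectory, model) {
  steps <- detect_steps(trajectory)
  seat_fy <- trajectory$seat_y
  seat_off <- NA_real_
  loaded <- which(seat_fy > 1)
  if (length(loaded)) {
    rel <- which(seat_fy <= 1 & seq_along(seat_fy) > min(loaded))
    if (length(rel)) seat_off <- trajectory$time[min(rel)]
  }
  vel <- gait_velocity_measure(trajectory, steps = steps)
  loads <- list()
  for (jt in c("hip", "knee", "ankle")) {
    for (leg in c("r", "l")) {
      nm <- paste0(jt, "_", leg)
      loads[[paste0("peak_load_", nm)]] <-
        max(joint_reaction_load(trajectory, model, nm)$force)
    }
  }
  # stepping leg: the leg swinging first after the gait transition
  stepping <- if (nrow(steps)) steps$leg[1] else NA_character_
  c(list(
    peak_trunk_angle_standup = peak_trunk_angle(trajectory, "standup"),
    peak_trunk_angle_p1 = peak_trunk_angle(trajectory, "P1"),
    seat_off_time = seat_off,
    n_steps = nrow(steps),
    stepping_leg = stepping,
    gait_velocity = vel$v_bar,
    displacement = max(trajectory$pelvis_com_x) -
      trajectory$pelvis_com_x[1],
    end_time = max(trajectory$time),
    fell = isTRUE(attr(trajectory, "fell")),
    peak_tau_lumbar = max(abs(trajectory$tau_lumbar)),
    peak_tau_thoracic = max(abs(trajectory$tau_thoracic))),
    loads)
}

#' Compare two condition summaries
#'
#' Percent change of each shared numeric metric: `(alt - base)/base x 100`.
#' Note the antisymmetry caveat: swapping the roles changes the
#' denominator.
#'
#' @param baseline,alternative Summaries from [summarize_trajectory()].
#' @return Named vector of percent deltas.
#' @export
compare_conditions <- function(baseline, alternative) {
  keys <- intersect(names(baseline), names(alternative))
  keys <- keys[vapply(keys, function(k) {
    is.numeric(baseline[[k]]) && is.finite(baseline[[k]]) &&
      is.numeric(alternative[[k]]) && baseline[[k]] != 0
  }, logical(1))]
  vapply(keys, function(k) {
    (alternative[[k]] - baseline[[k]]) / baseline[[k]] * 100
  }, numeric(1))
}

#' Write a result bundle
#'
#' Writes the trajectory as CSV, the objective report and summary as
#' key/value text, and the controller parameters as a `.par` file.
#' Reloading the CSV reproduces the summary.
#'
#' @param dir Output directory (created if needed).
#' @param trajectory An `s2w_trajectory`.
#' @param model An `s2w_model`.
#' @param report Optional `s2w_objective_report`.
#' @param config Optional `s2w_controller`.
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(dir, trajectory, model, report = NULL,
                          config = NULL) {
  if (nrow(trajectory) == 0) stop("empty trajectory", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  tf <- file.path(dir, "trajectory.csv")
  df <- as.data.frame(trajectory)
  attr(df, "end_time") <- NULL
  utils::write.csv(df, tf, row.names = FALSE)
  mf <- file.path(dir, "trajectory_meta.txt")
  writeLines(sprintf("%s\t%.17g", c("end_time", "T1", "T2", "fell"),
                     c(attr(trajectory, "end_time"),
                       attr(trajectory, "T1"), attr(trajectory, "T2"),
                       as.numeric(isTRUE(attr(trajectory, "fell"))))), mf)
  files <- c(files, tf, mf)
  kv <- function(x) paste(names(x), vapply(x, function(v)
    paste(format(v, digits = 17), collapse = " "), character(1)),
    sep = "\t")
  sf <- file.path(dir, "summary.txt")
  writeLines(kv(summarize_trajectory(trajectory, model)), sf)
  files <- c(files, sf)
  if (!is.null(report)) {
    of <- file.path(dir, "objective.txt")
    writeLines(kv(unclass(report)), of)
    files <- c(files, of)
  }
  if (!is.null(config)) {
    pf <- file.path(dir, "best.par")
    write_par_file(config, pf)
    files <- c(files, pf)
  }
  invisible(files)
}

#' Reload a trajectory CSV
#'
#' @param path CSV written by [write_results()].
#' @param T1,T2 Phase transition times to re-attach (s).
#' @return An `s2w_trajectory`.
#' @export
read_trajectory <- function(path, T1 = NA_real_, T2 = NA_real_) {
  df <- utils::read.csv(path)
  fell <- FALSE
  end_time <- max(df$time)
  mf <- file.path(dirname(path), "trajectory_meta.txt")
  if (file.exists(mf)) {
    kv <- strsplit(readLines(mf), "\t")
    vals <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]),
                                   numeric(1)),
                            vapply(kv, `[[`, character(1), 1))
    end_time <- vals[["end_time"]]
    if (is.na(T1)) T1 <- vals[["T1"]]
    if (is.na(T2)) T2 <- vals[["T2"]]
    fell <- vals[["fell"]] > 0
  }
  if (is.na(T2) && any(df$phase == 2)) T2 <- min(df$time[df$phase == 2])
  if (is.na(T1) && any(df$phase >= 1)) T1 <- min(df$time[df$phase >= 1])
  structure(df, class = c("s2w_trajectory", "data.frame"),
            fell = fell, end_time = end_time, T1 = T1, T2 = T2)
}
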