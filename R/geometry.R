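# Muscle-path geometry and joint-limit torques (R surface over the engine).

.resolve_q <- function(model, q) {
  if (!is.null(names(q))) {
    miss <- setdiff(model$coords, names(q))
    if (length(miss)) stop("posture is missing coordinate(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    q <- q[model$coords]
  }
  if (length(q) != model$dof_count) {
    stop("q must have ", model$dof_count, " entries", call. = FALSE)
  }
  as.numeric(q)
}

.muscle_index <- function(model, muscle) {
  i <- match(muscle, model$muscles$name)
  if (is.na(i)) stop("unknown muscle: ", muscle, call. = FALSE)
  i
}

#' Muscle-tendon length
#'
#' Total path length of a muscle-tendon unit: the sum of Euclidean distances
#' between consecutive via-points resolved to the ground frame.
#'
#' @param model An `s2w_model`.
#' @param q Generalized coordinates (rad, m), ordered as `model$coords` or
#'   named.
#' @param muscle Muscle name (e.g. `"sol_r"`); if NULL, all lengths are
#'   returned as a named vector.
#' @return Length(s) in metres.
#' @export
muscle_tendon_length <- function(model, q, muscle = NULL) {
  q <- .resolve_q(model, q)
  g <- cpp_muscle_geometry(model$engine, q)
  len <- stats::setNames(g$length, model$muscles$name)
  if (is.null(muscle)) return(len)
  len[[.muscle_index(model, muscle)]]
}

#' Muscle moment arm about a joint
#'
#' Tendon-excursion moment arm, -dL/dq (metres per radian): positive when
#' positive muscle force produces a positive generalized torque about the
#' coordinate.
#'
#' @inheritParams muscle_tendon_length
#' @param muscle Muscle name.
#' @param joint Pin-joint / coordinate name (e.g. `"knee_r"`).
#' @return Moment arm in metres; 0 with a warning when the muscle does not
#'   span the joint.
#' @export
moment_arm <- function(model, q, muscle, joint) {
  q <- .resolve_q(model, q)
  mi <- .muscle_index(model, muscle)
  ji <- match(joint, model$coords)
  if (is.na(ji)) stop("unknown coordinate: ", joint, call. = FALSE)
  # structural spanning check: the joint's child body must separate the path
  child <- match(model$joints$child[model$joints$name == joint],
                 model$body_names)
  if (length(child) == 1 && !is.na(child)) {
    vp <- model$viapoints[model$viapoints$muscle == muscle, , drop = FALSE]
    bidx <- match(vp$segment, model$body_names)
    in_subtree <- vapply(bidx, function(b) {
      while (!is.na(b) && b > 0) {
        if (b == child) return(TRUE)
        b <- model$parent[b]
        if (b == 0) break
      }
      FALSE
    }, logical(1))
    if (all(in_subtree) || !any(in_subtree)) {
      warning("muscle ", muscle, " does not span joint ", joint)
      return(0)
    }
  }
  g <- cpp_muscle_geometry(model$engine, q)
  g$moment_arm[mi, ji]
}

#' Joint limit torque
#'
#' Ligament-like restoring torque outside a coordinate's range: zero within
#' the range, `-k * excess - c * qdot * ramp` outside, where the short
#' damping ramp (full within 0.02 rad of excess) keeps the torque continuous
#' at the boundary.
#'
#' @inheritParams muscle_tendon_length
#' @param joint Coordinate name.
#' @param angle Coordinate value (rad).
#' @param velocity Coordinate velocity (rad/s).
#' @return Torque in N m, directed into the range.
#' @export
joint_limit_torque <- function(model, joint, angle, velocity = 0) {
  ji <- match(joint, model$coords)
  if (is.na(ji)) stop("unknown coordinate: ", joint, call. = FALSE)
  vapply(seq_along(angle), function(i) {
    cpp_limit_torque(angle[i], velocity[min(i, length(velocity))],
                     model$qmin[ji], model$qmax[ji],
                     model$limit_k[ji], model$limit_c[ji])
  }, numeric(1))
}

#' Body poses at a posture
#'
#' @inheritParams muscle_tendon_length
#' @return Matrix (bodies x 3): world x, y of each segment frame origin and
#'   its CCW orientation (rad), rows named by segment.
#' @export
body_poses <- function(model, q) {
  q <- .resolve_q(model, q)
  p <- cpp_body_poses(model$engine, q)
  dimnames(p) <- list(model$body_names, c("x", "y", "theta"))
  p
}
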