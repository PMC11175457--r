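# Hunt-Crossley compliant contact and regularized friction (R surface).

#' Hunt-Crossley normal force
#'
#' `k * x^(3/2) * (1 + 1.5 c xdot)` for positive penetration, clamped below
#' at zero (no adhesion), zero otherwise.
#'
#' @param x Penetration (m).
#' @param xdot Penetration rate (m/s, increasing penetration positive).
#' @param k Hertz coefficient (N/m^1.5), see [contact_stiffness()].
#' @param c Dissipation coefficient (s/m).
#' @return Normal force (N), non-negative.
#' @export
normal_force <- function(x, xdot = 0, k, c = 1) {
  n <- max(length(x), length(xdot))
  cpp_normal_force(rep_len(x, n), rep_len(xdot, n), k, c)
}

#' Regularized friction force
#'
#' Velocity-regularized stick/slip friction: a tanh ramp (slip tolerance
#' 0.01 m/s) times a Stribeck decay from the static to the dynamic
#' coefficient.  The magnitude never exceeds `mu_s * N`; fast sliding gives
#' `mu_d * N` opposing the slip.
#'
#' @param N Normal force (N, non-negative).
#' @param v_t Tangential slip velocity (m/s).
#' @param mu_s,mu_d Static / dynamic friction coefficients.
#' @return Friction force (N), signed, opposing slip.
#' @export
friction_force <- function(N, v_t, mu_s = 0.9, mu_d = 0.6) {
  stopifnot(all(N >= 0), mu_s >= mu_d, mu_d >= 0)
  n <- max(length(N), length(v_t))
  cpp_friction_force(rep_len(N, n), rep_len(v_t, n), mu_s, mu_d)
}

#' Sphere-box contact query
#'
#' Closest-point computation between a sphere and an axis-aligned box
#' (planar rectangle cross-section), handling face and corner cases.
#'
#' @param center Sphere center (x, y).
#' @param radius Sphere radius (m).
#' @param box_center Box center (x, y).
#' @param half_extents Box half-extents (x, y).
#' @return List: `penetration` (m, positive when overlapping), `point`
#'   (contact point on the box surface), `normal` (unit vector from box
#'   into sphere).
#' @export
sphere_box_contact <- function(center, radius, box_center, half_extents) {
  cpp_sphere_box(center[1], center[2], radius,
                 box_center[1], box_center[2],
                 half_extents[1], half_extents[2])
}
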