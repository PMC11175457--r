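# Hill-type muscle-tendon unit: activation dynamics, curve family, and the
# contraction-dynamics step.  The curve family is a standard smooth Hill set
# anchored at active_force_length(1) = 1, force_velocity(0) = 1,
# force_velocity(-vmax) = 0, eccentric plateau 1.5, passive force 0 below
# optimal length, tendon force 0 at non-positive strain.

#' Activation rate
#'
#' First-order activation dynamics `da/dt = (u - a)/tau`, with
#' `tau = tau_act` (10 ms) when the excitation exceeds the activation and
#' `tau_deact` (40 ms) otherwise.
#'
#' @param u Excitation in \[0, 1\].
#' @param a Activation in \[0, 1\].
#' @param tau_act,tau_deact Activation / deactivation time constants (s).
#' @return Rate of activation change (1/s).
#' @export
activation_rate <- function(u, a, tau_act = 0.010, tau_deact = 0.040) {
  stopifnot(all(u >= 0 & u <= 1), all(a >= 0 & a <= 1))
  tau <- ifelse(u >= a, tau_act, tau_deact)
  (u - a) / tau
}

#' Hill curve family
#'
#' @param L Normalized contractile-element length (l_ce / l_opt).
#' @param v Normalized CE velocity as a fraction of v_max (lengthening
#'   positive), i.e. V / v_max.
#' @param strain Tendon strain (l_t - l_slack)/l_slack.
#' @return Dimensionless force scale.
#' @name hill_curves
NULL

#' @rdname hill_curves
#' @export
active_force_length <- function(L) {
  cpp_muscle_curves(L, rep(0, length(L)), 0)$fl
}

#' @rdname hill_curves
#' @export
force_velocity <- function(v) {
  cpp_muscle_curves(rep(1, length(v)), v, 0)$fv
}

#' @rdname hill_curves
#' @export
passive_force <- function(L) {
  cpp_muscle_curves(L, rep(0, length(L)), 0)$fpe
}

#' @rdname hill_curves
#' @export
tendon_force <- function(strain) {
  cpp_muscle_curves(1, 0, strain)$ft
}

#' Inverse force-velocity curve
#' @param f Force-velocity scale value.
#' @return Normalized velocity v = V/v_max with force_velocity(v) = f.
#' @export
force_velocity_inverse <- function(f) cpp_fv_inverse(f)

#' Advance a muscle-tendon unit one step
#'
#' Elastic-tendon contraction dynamics: the fiber velocity is obtained by
#' inverting the force-velocity relation against the tendon load
#' (CE--tendon force equilibrium), then the fiber length is advanced
#' explicitly.  In rigid-tendon mode the fiber length is `l_mt - l_slack`
#' and the normalized force follows in closed form (the analytic oracle
#' used by the tests).
#'
#' @param params One row of `model$muscles` or a list with `fmax`, `lopt`,
#'   `lslack`, `vmax`.
#' @param state List with `a` (activation) and `lce` (fiber length, m).
#' @param mtu_length Muscle-tendon length (m).
#' @param dt Time step (s).
#' @param rigid Use the rigid-tendon closed form.
#' @param mtu_length_prev Previous MTU length (rigid mode velocity).
#' @return List: `lce`, `L` (normalized length), `V` (normalized velocity,
#'   l_opt/s, lengthening positive), `F` (normalized force f_mtu/f_max),
#'   and updated `a`.
#' @export
mtu_step <- function(params, state, mtu_length, dt, rigid = FALSE,
                     mtu_length_prev = NA_real_) {
  stopifnot(dt > 0)
  out <- cpp_mtu_step(params$fmax, params$lopt, params$lslack, params$vmax,
                      state$a, state$lce, mtu_length, dt, rigid,
                      mtu_length_prev)
  out$a <- state$a
  out
}
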