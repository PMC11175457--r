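# Neural latency derivation for the reflex pathways.
#
# All latencies are carried on a 5 ms grid, the resolution supported by the
# physiological literature the constants come from.  Three families exist:
#   * monosynaptic: a muscle's own spindle/GTO loop,
#   * antagonistic: crossed inhibition from an opposing muscle,
#   * vestibular:   pelvis-orientation feedback routed to the muscle.

#' Physiological constants anchoring the latency derivation
#'
#' @return Named list: \code{h_reflex_ms} (soleus H-reflex latency),
#'   \code{distal_motor_ms} (distal motor latency), \code{cv_m_per_s}
#'   (motor axon conduction velocity), \code{gmax_sol_distance_m}
#'   (difference in motor distance between GMAX and SOL, midpoint of the
#'   0.50--0.60 m estimate), \code{patellar_reflex_ms},
#'   \code{sol_vestibular_ms} (soleus short-latency vestibular response),
#'   \code{thoracic_vestibular_ms}.
#' @export
latency_constants <- function() {
  list(
    h_reflex_ms          = 30.2,
    distal_motor_ms      = 3.3,
    cv_m_per_s           = 50,
    gmax_sol_distance_m  = 0.55,
    patellar_reflex_ms   = 21,
    sol_vestibular_ms    = 55,
    thoracic_vestibular_ms = 30,
    grid_ms              = 5
  )
}

.muscle_names <- c("HAM", "BFSH", "GMAX", "ILIAC", "PSOAS",
                   "RFEM", "VAS", "GAS", "SOL", "TA")

.antagonist_map <- list(
  HAM   = c("RFEM", "VAS"),
  BFSH  = c("RFEM", "VAS"),
  GMAX  = c("ILIAC", "PSOAS"),
  ILIAC = "GMAX",
  PSOAS = "GMAX",
  RFEM  = c("HAM", "BFSH"),
  VAS   = c("HAM", "BFSH"),
  GAS   = "TA",
  SOL   = "TA",
  TA    = c("GAS", "SOL")
)

#' Muscle groups of the planar model (one side)
#' @return Character vector of the ten muscle group labels.
#' @export
muscle_groups <- function() .muscle_names

#' Antagonist muscle groups
#' @param muscle Muscle group label.
#' @return Character vector of antagonist labels.
#' @export
antagonists_of <- function(muscle) {
  m <- match.arg(toupper(muscle), .muscle_names)
  .antagonist_map[[m]]
}

round5_nearest <- function(x) 5 * floor(x / 5 + 0.5)   # half rounds up
round5_down    <- function(x) 5 * floor(x / 5 + 1e-9)  # tolerate fp noise at grid points

#' Monosynaptic reflex latency
#'
#' The soleus loop time is the measured H-reflex latency plus the distal
#' motor latency, rounded to the 5 ms grid; GAS and TA share it (similar
#' loop length).  Proximal muscles (GMAX, ILIAC, PSOAS) subtract twice the
#' motor-distance difference over the conduction velocity and are floored
#' to the grid.  RFEM comes from the patellar tendon reflex; VAS and BFSH
#' share its path length; HAM is one grid step shorter.
#'
#' @param muscle Muscle group label (see [muscle_groups()]).
#' @param constants Constant set, see [latency_constants()].
#' @return Latency in ms (multiple of 5).
#' @export
derive_monosynaptic_latency <- function(muscle, constants = latency_constants()) {
  m <- match.arg(toupper(muscle), .muscle_names)
  sol <- round5_nearest(constants$h_reflex_ms + constants$distal_motor_ms)
  switch(m,
    SOL = ,
    GAS = ,
    TA  = sol,
    GMAX = ,
    ILIAC = ,
    PSOAS = round5_down(
      sol - 2 * constants$gmax_sol_distance_m / constants$cv_m_per_s * 1000),
    RFEM = ,
    VAS  = ,
    BFSH = round5_nearest(constants$patellar_reflex_ms),
    HAM  = round5_nearest(constants$patellar_reflex_ms) - constants$grid_ms
  )
}

#' Antagonistic reflex latency
#'
#' Mean of the monosynaptic delays of the two muscles involved, rounded to
#' the nearest multiple of 5 ms (halves round up: a 17.5 ms mean maps to
#' 20 ms).  With several antagonists the rounded mean over all pairs is
#' returned (all tabulated pairs agree after rounding).
#'
#' @param muscle Target muscle group label.
#' @param antagonists Antagonist labels; defaults to the model's wiring.
#' @inheritParams derive_monosynaptic_latency
#' @return Latency in ms (multiple of 5).
#' @export
derive_antagonistic_latency <- function(muscle,
                                        antagonists = antagonists_of(muscle),
                                        constants = latency_constants()) {
  m <- match.arg(toupper(muscle), .muscle_names)
  own <- derive_monosynaptic_latency(m, constants)
  per_pair <- vapply(antagonists, function(a) {
    (own + derive_monosynaptic_latency(a, constants)) / 2
  }, numeric(1))
  round5_nearest(mean(per_pair))
}

#' Vestibular feedback latency
#'
#' The soleus short-latency vestibular response (55 ms) spans the central
#' path plus one motor distance; half the monosynaptic loop delay is a
#' proxy for the one-way motor distance, so for a muscle with monosynaptic
#' delay dt the vestibular latency is 55 - 35/2 + dt/2, rounded down to
#' the 5 ms grid.  The lumbar joint uses 55 - 35/2 (no muscle loop);
#' the thoracic joint uses a 30 ms central estimate.
#'
#' @param muscle_or_joint Muscle group label, `"lumbar"`, or `"thoracic"`.
#' @inheritParams derive_monosynaptic_latency
#' @return Latency in ms (multiple of 5).
#' @export
derive_vestibular_latency <- function(muscle_or_joint,
                                      constants = latency_constants()) {
  key <- toupper(muscle_or_joint)
  sol_vest <- constants$sol_vestibular_ms
  sol_mono <- derive_monosynaptic_latency("SOL", constants)
  if (key == "LUMBAR") {
    return(round5_down(sol_vest - sol_mono / 2))
  }
  if (key %in% c("THORACIC", "THORAX")) {
    return(constants$thoracic_vestibular_ms)
  }
  m <- match.arg(key, .muscle_names)
  dt <- derive_monosynaptic_latency(m, constants)
  round5_down(sol_vest - sol_mono / 2 + dt / 2)
}

#' Full latency table
#'
#' Derives the complete per-muscle latency table (monosynaptic,
#' antagonistic, vestibular) plus the lumbar and thoracic vestibular rows.
#'
#' @inheritParams derive_monosynaptic_latency
#' @return data.frame with columns `unit`, `monosynaptic_ms`,
#'   `antagonistic_ms`, `vestibular_ms` (NA where a pathway does not exist).
#' @export
latency_table <- function(constants = latency_constants()) {
  mono <- vapply(.muscle_names, derive_monosynaptic_latency, numeric(1),
                 constants = constants)
  anta <- vapply(.muscle_names, derive_antagonistic_latency, numeric(1),
                 constants = constants)
  vest <- vapply(.muscle_names, derive_vestibular_latency, numeric(1),
                 constants = constants)
  data.frame(
    unit = c(.muscle_names, "lumbar", "thoracic"),
    monosynaptic_ms = c(mono, NA, NA),
    antagonistic_ms = c(anta, NA, NA),
    vestibular_ms = c(vest,
                      derive_vestibular_latency("lumbar", constants),
                      derive_vestibular_latency("thoracic", constants)),
    row.names = NULL
  )
}
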