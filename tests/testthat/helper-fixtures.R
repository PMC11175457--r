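# Programmatic fixtures: reduced model files written to tempfiles.

write_model_lines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# single rigid ball on a planar-free joint, one contact sphere
ball_model <- function(radius = 0.1, modulus = 17500, mass = 1) {
  f <- write_model_lines(c(
    "model ball",
    "gravity 9.81",
    sprintf("segment ball mass=%g inertia=0.004 com=0,0 length=0.2", mass),
    "joint ground_ball type=free parent=ground child=ball",
    sprintf("sphere s segment=ball pos=0,0 radius=%g modulus=%g dissipation=1 mu_s=0.9 mu_d=0.6",
            radius, modulus)))
  build_model(f, expect_dof = 3, expect_muscles = 0, expect_mass = NA)
}

# two links connected by one pin joint, one muscle crossing it
two_link_model <- function(p1 = c(0.10, -0.20), p2 = c(0.05, -0.10),
                           joint_pos = c(0, -0.5)) {
  f <- write_model_lines(c(
    "model twolink",
    "gravity 9.81",
    "segment link1 mass=2 inertia=0.05 com=0,-0.25 length=0.5",
    "segment link2 mass=1 inertia=0.02 com=0,-0.2 length=0.4",
    "joint ground_link1 type=free parent=ground child=link1",
    sprintf("joint elbow type=pin parent=link1 child=link2 pos=%g,%g sign=1 range=-170,170 limit_stiffness=500 limit_damping=0.5",
            joint_pos[1], joint_pos[2]),
    "muscle m1 fmax=1000 lopt=0.1 lslack=0.2 vmax=10 side=r",
    sprintf("viapoint m1 link1 %g,%g", p1[1], p1[2]),
    sprintf("viapoint m1 link2 %g,%g", p2[1], p2[2])))
  build_model(f, expect_dof = 4, expect_muscles = 1, expect_mass = NA)
}

# synthetic trajectory with all channels present, defaulting to zeros
make_traj <- function(time, model = NULL, ..., T1 = NA_real_, T2 = NA_real_,
                      fell = FALSE, end_time = max(time)) {
  coords <- c("pelvis_tx", "pelvis_ty", "pelvis_tilt", "lumbar", "thoracic",
              "hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l")
  mus <- as.vector(outer(c("gmax", "ham", "bfsh", "iliac", "psoas", "rfem",
                           "vas", "gas", "sol", "ta"),
                         c("r", "l"), paste, sep = "_"))
  cols <- c("time", paste0("q_", coords), paste0("qd_", coords),
            paste0("act_", mus), paste0("exc_", mus), paste0("L_", mus),
            paste0("V_", mus), paste0("F_", mus),
            "grf_r_x", "grf_r_y", "grf_l_x", "grf_l_y", "seat_x", "seat_y",
            "pelvis_com_x", "pelvis_com_y", "com_x", "com_y",
            "head_x", "head_y", "heel_r_fy", "heel_l_fy",
            "tau_lumbar", "tau_thoracic", "phase", "state_r", "state_l")
  df <- as.data.frame(matrix(0, length(time), length(cols),
                             dimnames = list(NULL, cols)))
  df$time <- time
  df[["L_gmax_r"]] <- 1  # harmless defaults
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  structure(df, class = c("s2w_trajectory", "data.frame"),
            fell = fell, end_time = end_time, T1 = T1, T2 = T2,
            scenario = structure(sitwalk:::.scenario_defaults(),
                                 class = "s2w_scenario"))
}

default_model_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_model()
    m
  }
})

# exact mechanical energy at a state (FD Jacobian), used by the
# conservation checks
total_energy <- function(model, q, qd) {
  segs <- model$segments
  h <- 1e-6
  comw <- function(q) {
    p <- body_poses(model, q)
    cbind(p[, 1] + cos(p[, 3]) * segs$com_x - sin(p[, 3]) * segs$com_y,
          p[, 2] + sin(p[, 3]) * segs$com_x + cos(p[, 3]) * segs$com_y,
          p[, 3])
  }
  nb <- nrow(segs); nd <- model$dof_count
  J <- array(0, c(nb, 3, nd))
  for (j in seq_len(nd)) {
    qa <- q; qa[j] <- q[j] + h
    qb <- q; qb[j] <- q[j] - h
    J[, , j] <- (comw(qa) - comw(qb)) / (2 * h)
  }
  KE <- 0
  for (b in seq_len(nb)) {
    v <- c(sum(J[b, 1, ] * qd), sum(J[b, 2, ] * qd))
    w <- sum(J[b, 3, ] * qd)
    KE <- KE + 0.5 * segs$mass[b] * sum(v^2) + 0.5 * segs$inertia[b] * w^2
  }
  cw <- comw(q)
  KE + sum(segs$mass * model$gravity * cw[, 2])
}

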