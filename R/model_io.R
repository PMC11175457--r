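# Model-definition file parsing and model construction.
#
# The model file is line-oriented structured text (units: m, kg, deg).
# Record types:
#   model <name>
#   gravity <m/s^2>
#   segment <name> mass=<kg> inertia=<kg m^2> com=<x>,<y> length=<m>
#   joint <name> type={free|pin} parent=<seg> child=<seg> pos=<x>,<y>
#         [sign=<+1|-1>] [range=<min>,<max>] [limit_stiffness=<Nm/rad>]
#         [limit_damping=<Nm s/rad>] [tilt_sign=<+1|-1>]
#   muscle <name> fmax=<N> lopt=<m> lslack=<m> vmax=<lopt/s> side={r|l}
#   viapoint <muscle> <segment> <x>,<y>          (ordered, proximal first)
#   sphere <name> segment=<seg> pos=<x>,<y> radius=<m> modulus=<N/m^2>
#          dissipation=<s/m> mu_s=<..> mu_d=<..> [role={foot|buttock}]
#   box <name> size=<x>,<y> modulus=<N/m^2> dissipation=<s/m> mu_s=.. mu_d=..
# `pos` of a pin joint is the joint location in the parent frame; the child
# frame origin sits at the joint.  `sign` maps the user coordinate (gait
# convention: flexion/dorsiflexion/anterior-tilt positive) onto the internal
# counter-clockwise rotation.

.parse_kv <- function(tokens, record, lineno) {
  out <- list()
  for (tok in tokens) {
    if (!grepl("=", tok, fixed = TRUE)) {
      stop(sprintf("model file line %d (%s): malformed field '%s'",
                   lineno, record, tok), call. = FALSE)
    }
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(strsplit(kv[2], ",", fixed = TRUE)[[1]]))
    if (anyNA(val)) val <- kv[2]
    out[[kv[1]]] <- val
  }
  out
}

.require_fields <- function(kv, fields, record, lineno) {
  miss <- setdiff(fields, names(kv))
  if (length(miss) > 0) {
    stop(sprintf("model file line %d (%s): missing field(s) %s",
                 lineno, record, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Parse a model-definition file
#'
#' Reads the structured-text model file into raw record tables without
#' validating counts; [build_model()] performs construction and validation.
#'
#' @param path Path to the model-definition file.
#' @return List of record tables (segments, joints, muscles, viapoints,
#'   spheres, boxes, gravity, name).
#' @export
parse_model_file <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  segs <- list(); joints <- list(); muscles <- list()
  vps <- list(); spheres <- list(); boxes <- list()
  gravity <- 9.81; name <- "model"
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (nchar(line) == 0) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    rec <- tok[1]
    if (rec == "model") {
      name <- tok[2]
    } else if (rec == "gravity") {
      gravity <- as.numeric(tok[2])
    } else if (rec == "segment") {
      kv <- .parse_kv(tok[-(1:2)], rec, i)
      .require_fields(kv, c("mass", "inertia", "com", "length"), rec, i)
      segs[[length(segs) + 1]] <- data.frame(
        name = tok[2], mass = kv$mass, inertia = kv$inertia,
        com_x = kv$com[1], com_y = kv$com[2], length = kv$length)
    } else if (rec == "joint") {
      kv <- .parse_kv(tok[-(1:2)], rec, i)
      .require_fields(kv, c("type", "parent", "child"), rec, i)
      if (identical(kv$type, "pin")) .require_fields(kv, c("pos", "range"), rec, i)
      joints[[length(joints) + 1]] <- data.frame(
        name = tok[2], type = kv$type, parent = kv$parent, child = kv$child,
        px = if (is.null(kv$pos)) 0 else kv$pos[1],
        py = if (is.null(kv$pos)) 0 else kv$pos[2],
        sign = if (is.null(kv$sign)) 1 else kv$sign,
        tilt_sign = if (is.null(kv$tilt_sign)) 1 else kv$tilt_sign,
        qmin_deg = if (is.null(kv$range)) -Inf else kv$range[1],
        qmax_deg = if (is.null(kv$range)) Inf else kv$range[2],
        limit_k = if (is.null(kv$limit_stiffness)) 500 else kv$limit_stiffness,
        limit_c = if (is.null(kv$limit_damping)) 0.5 else kv$limit_damping,
        passive = if (is.null(kv$passive)) 0 else kv$passive)
    } else if (rec == "muscle") {
      kv <- .parse_kv(tok[-(1:2)], rec, i)
      .require_fields(kv, c("fmax", "lopt", "lslack", "vmax", "side"), rec, i)
      muscles[[length(muscles) + 1]] <- data.frame(
        name = tok[2], fmax = kv$fmax, lopt = kv$lopt, lslack = kv$lslack,
        vmax = kv$vmax, side = kv$side)
    } else if (rec == "viapoint") {
      xy <- as.numeric(strsplit(tok[4], ",", fixed = TRUE)[[1]])
      if (length(xy) != 2 || anyNA(xy)) {
        stop(sprintf("model file line %d (viapoint): bad coordinates '%s'",
                     i, tok[4]), call. = FALSE)
      }
      vps[[length(vps) + 1]] <- data.frame(
        muscle = tok[2], segment = tok[3], x = xy[1], y = xy[2])
    } else if (rec == "sphere") {
      kv <- .parse_kv(tok[-(1:2)], rec, i)
      .require_fields(kv, c("segment", "pos", "radius", "modulus",
                            "dissipation", "mu_s", "mu_d"), rec, i)
      spheres[[length(spheres) + 1]] <- data.frame(
        name = tok[2], segment = kv$segment, x = kv$pos[1], y = kv$pos[2],
        radius = kv$radius, modulus = kv$modulus,
        dissipation = kv$dissipation, mu_s = kv$mu_s, mu_d = kv$mu_d,
        role = if (is.null(kv$role)) "foot" else kv$role)
    } else if (rec == "box") {
      kv <- .parse_kv(tok[-(1:2)], rec, i)
      .require_fields(kv, c("size", "modulus", "dissipation", "mu_s", "mu_d"),
                      rec, i)
      boxes[[length(boxes) + 1]] <- data.frame(
        name = tok[2], size_x = kv$size[1], size_y = kv$size[2],
        modulus = kv$modulus, dissipation = kv$dissipation,
        mu_s = kv$mu_s, mu_d = kv$mu_d)
    } else {
      stop(sprintf("model file line %d: unknown record type '%s'", i, rec),
           call. = FALSE)
    }
  }
  list(name = name, gravity = gravity,
       segments = do.call(rbind, segs), joints = do.call(rbind, joints),
       muscles = do.call(rbind, muscles), viapoints = do.call(rbind, vps),
       spheres = do.call(rbind, spheres), boxes = do.call(rbind, boxes))
}

#' Effective Hunt-Crossley stiffness from a plane-strain modulus
#'
#' The Hertz sphere-on-plane coefficient is k = 4/3 E* sqrt(R), so that the
#' normal force is k x^(3/2).  The printed plane-strain moduli of the model
#' (17500 N/m^2 feet, 10000 N/m^2 chair) are kept verbatim in the fixture;
#' because the source engine's parameter semantics are not documented, a
#' single dimensionless stiffness scale (default 300, calibrated once so
#' that quiet standing penetrates about 3 mm) bridges the unit convention.
#'
#' @param modulus Plane-strain modulus E* (N/m^2, as printed).
#' @param radius Sphere radius (m).
#' @param scale Stiffness scale factor (dimensionless).
#' @return Hertz coefficient k in N/m^(3/2).
#' @export
contact_stiffness <- function(modulus, radius, scale = 300) {
  4 / 3 * modulus * sqrt(radius) * scale
}

#' Path to the shipped planar sit-to-walk model definition
#' @return File path of the default model fixture.
#' @export
default_model_file <- function() {
  system.file("extdata", "h1120_planar.txt", package = "sitwalk",
              mustWork = TRUE)
}

#' Build the planar musculoskeletal model
#'
#' Parses a model-definition file and assembles the simulation-ready model:
#' kinematic tree, coordinate list, muscle paths, and contact elements.
#' Construction validates the structural contract of the planar sit-to-walk
#' model: exactly one free (planar, 3-DOF) pelvis-ground connection, 11
#' generalized coordinates in total, 20 muscle-tendon units, and a total
#' mass of 75 kg (tolerance 1e-6).
#'
#' @param definition_file Path to the model file; defaults to the shipped
#'   fixture.
#' @param expect_dof,expect_muscles,expect_mass Structural expectations;
#'   set to NA to skip a check (used for reduced test models).
#' @return An object of class `s2w_model`.
#' @export
build_model <- function(definition_file = default_model_file(),
                        expect_dof = 11, expect_muscles = 20,
                        expect_mass = 75) {
  raw <- parse_model_file(definition_file)
  segs <- raw$segments; joints <- raw$joints
  if (is.null(segs) || is.null(joints)) {
    stop("model file must define segments and joints", call. = FALSE)
  }
  if (any(segs$mass <= 0) || any(segs$inertia <= 0)) {
    stop("segment masses and inertias must be positive", call. = FALSE)
  }
  free <- joints[joints$type == "free", , drop = FALSE]
  if (nrow(free) != 1) {
    stop("model must contain exactly one free (pelvis-ground) joint, found ",
         nrow(free), call. = FALSE)
  }
  pins <- joints[joints$type == "pin", , drop = FALSE]
  dof <- 3 + nrow(pins)
  if (!is.na(expect_dof) && dof != expect_dof) {
    stop(sprintf("model construction: DOF = %d, expected %d", dof, expect_dof),
         call. = FALSE)
  }
  n_mus <- if (is.null(raw$muscles)) 0 else nrow(raw$muscles)
  if (!is.na(expect_muscles) && n_mus != expect_muscles) {
    stop(sprintf("model construction: muscle count = %d, expected %d",
                 n_mus, expect_muscles), call. = FALSE)
  }
  total_mass <- sum(segs$mass)
  if (!is.na(expect_mass) && abs(total_mass - expect_mass) > 1e-6) {
    stop(sprintf("model construction: total mass %.6f kg, expected %g",
                 total_mass, expect_mass), call. = FALSE)
  }

  root <- free$child
  # body order: root first, then depth-first over pin joints in file order
  body_names <- root
  repeat {
    grow <- pins$child[pins$parent %in% body_names &
                       !(pins$child %in% body_names)]
    if (length(grow) == 0) break
    body_names <- c(body_names, grow)
  }
  if (!setequal(body_names, segs$name)) {
    stop("kinematic tree does not span the segment set; orphan segment(s): ",
         paste(setdiff(segs$name, body_names), collapse = ", "), call. = FALSE)
  }
  bidx <- function(s) match(s, body_names)

  coords <- c("pelvis_tx", "pelvis_ty", "pelvis_tilt", pins$name)
  nb <- length(body_names)
  parent <- integer(nb); jx <- numeric(nb); jy <- numeric(nb)
  jsign <- numeric(nb); qindex <- integer(nb)
  qmin <- rep(-Inf, dof); qmax <- rep(Inf, dof)
  limit_k <- rep(0, dof); limit_c <- rep(0, dof); passive_c <- rep(0, dof)
  parent[1] <- 0L; jsign[1] <- free$tilt_sign
  for (k in seq_len(nrow(pins))) {
    b <- bidx(pins$child[k])
    parent[b] <- bidx(pins$parent[k])
    jx[b] <- pins$px[k]; jy[b] <- pins$py[k]
    jsign[b] <- pins$sign[k]
    qindex[b] <- 3L + k
    qmin[3 + k] <- pins$qmin_deg[k] * pi / 180
    qmax[3 + k] <- pins$qmax_deg[k] * pi / 180
    limit_k[3 + k] <- pins$limit_k[k]
    limit_c[3 + k] <- pins$limit_c[k]
    passive_c[3 + k] <- pins$passive[k]
  }

  mus <- raw$muscles
  vps <- raw$viapoints
  if (n_mus > 0) {
    for (mname in mus$name) {
      pth <- vps[vps$muscle == mname, , drop = FALSE]
      if (nrow(pth) < 2) {
        stop("muscle ", mname, " needs at least 2 via-points", call. = FALSE)
      }
      if (length(unique(pth$segment)) < 2) {
        stop("muscle ", mname, " must span at least one joint", call. = FALSE)
      }
      bad <- setdiff(pth$segment, body_names)
      if (length(bad)) {
        stop("muscle ", mname, " references unknown segment ", bad[1],
             call. = FALSE)
      }
    }
    if (any(mus$fmax <= 0) || any(mus$lopt <= 0) || any(mus$lslack <= 0)) {
      stop("muscle fmax, lopt, lslack must be positive", call. = FALSE)
    }
  }

  sph <- raw$spheres
  model <- structure(list(
    name = raw$name, gravity = raw$gravity,
    segments = segs[match(body_names, segs$name), , drop = FALSE],
    joints = joints, muscles = mus, viapoints = vps,
    spheres = sph, box = raw$boxes,
    body_names = body_names, coords = coords,
    dof_count = dof, muscle_count = n_mus, total_mass = total_mass,
    parent = parent, joint_x = jx, joint_y = jy, joint_sign = jsign,
    qindex = qindex, qmin = qmin, qmax = qmax,
    limit_k = limit_k, limit_c = limit_c, passive_c = passive_c
  ), class = "s2w_model")
  model$engine <- .engine_arrays(model)
  model
}

# flat 0-based arrays consumed by the compiled engine
.engine_arrays <- function(model) {
  nb <- length(model$body_names)
  segs <- model$segments
  e <- list(
    nb = nb,
    parent = as.integer(model$parent - 1L),       # -1 for root
    jx = model$joint_x, jy = model$joint_y,
    jsign = model$joint_sign,
    qindex = as.integer(model$qindex - 1L),       # -1 for root
    mass = segs$mass, inertia = segs$inertia,
    comx = segs$com_x, comy = segs$com_y,
    qmin = model$qmin, qmax = model$qmax,
    limit_k = model$limit_k, limit_c = model$limit_c,
    passive = model$passive_c,
    gravity = model$gravity,
    ndof = model$dof_count
  )
  mus <- model$muscles
  if (!is.null(mus) && nrow(mus) > 0) {
    vp <- model$viapoints
    starts <- integer(nrow(mus) + 1); starts[1] <- 0L
    vbody <- integer(0); vx <- numeric(0); vy <- numeric(0)
    for (k in seq_len(nrow(mus))) {
      pth <- vp[vp$muscle == mus$name[k], , drop = FALSE]
      vbody <- c(vbody, match(pth$segment, model$body_names) - 1L)
      vx <- c(vx, pth$x); vy <- c(vy, pth$y)
      starts[k + 1] <- length(vbody)
    }
    e$nm <- nrow(mus)
    e$fmax <- mus$fmax; e$lopt <- mus$lopt
    e$lslack <- mus$lslack; e$vmax <- mus$vmax
    e$vp_start <- as.integer(starts)
    e$vp_body <- as.integer(vbody); e$vp_x <- vx; e$vp_y <- vy
  } else {
    e$nm <- 0L
    e$fmax <- numeric(0); e$lopt <- numeric(0)
    e$lslack <- numeric(0); e$vmax <- numeric(0)
    e$vp_start <- 0L; e$vp_body <- integer(0)
    e$vp_x <- numeric(0); e$vp_y <- numeric(0)
  }
  sph <- model$spheres
  if (!is.null(sph) && nrow(sph) > 0) {
    e$ns <- nrow(sph)
    e$sp_body <- as.integer(match(sph$segment, model$body_names) - 1L)
    e$sp_x <- sph$x; e$sp_y <- sph$y; e$sp_r <- sph$radius
    e$sp_k <- contact_stiffness(sph$modulus, sph$radius)
    e$sp_c <- sph$dissipation
    e$sp_mus <- sph$mu_s; e$sp_mud <- sph$mu_d
    e$sp_buttock <- as.integer(sph$role == "buttock")
  } else {
    e$ns <- 0L
    e$sp_body <- integer(0); e$sp_x <- numeric(0); e$sp_y <- numeric(0)
    e$sp_r <- numeric(0); e$sp_k <- numeric(0); e$sp_c <- numeric(0)
    e$sp_mus <- numeric(0); e$sp_mud <- numeric(0); e$sp_buttock <- integer(0)
  }
  if (!is.null(model$box) && nrow(model$box) > 0) {
    bx <- model$box[1, ]
    butt_r <- if (any(e$sp_buttock == 1L)) e$sp_r[which(e$sp_buttock == 1L)[1]] else 0.12
    e$box_hx <- bx$size_x / 2; e$box_hy <- bx$size_y / 2
    # cushion-soft seat: a tenth of the foot stiffness scale, so the seat
    # contact mode (~15 rad/s) stays controllable through 40-55 ms delays
    e$box_k <- contact_stiffness(bx$modulus, butt_r, scale = 30)
    e$box_c <- bx$dissipation; e$box_mus <- bx$mu_s; e$box_mud <- bx$mu_d
  } else {
    e$box_hx <- 0; e$box_hy <- 0; e$box_k <- 0; e$box_c <- 1
    e$box_mus <- 0.9; e$box_mud <- 0.6
  }
  e
}

#' @export
print.s2w_model <- function(x, ...) {
  cat(sprintf("<s2w_model> %s: %d bodies, %d DOF, %d muscles, %.3f kg\n",
              x$name, length(x$body_names), x$dof_count, x$muscle_count,
              x$total_mass))
  invisible(x)
}

#' Model summary for the command line
#'
#' Prints DOF count, the muscle parameter table, and the mass check in the
#' format used by `s2w model-info`.
#'
#' @param model An `s2w_model` object.
#' @return Invisibly, a list with `dof`, `muscles`, `mass`.
#' @export
model_info <- function(model) {
  cat(sprintf("model: %s\n", model$name))
  cat(sprintf("degrees of freedom: %d\n", model$dof_count))
  cat(sprintf("total mass: %.3f kg\n", model$total_mass))
  cat(sprintf("muscle-tendon units: %d\n", model$muscle_count))
  if (model$muscle_count > 0) {
    print(model$muscles, row.names = FALSE)
  }
  invisible(list(dof = model$dof_count, muscles = model$muscles,
                 mass = model$total_mass))
}
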