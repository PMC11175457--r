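# Shooting optimization of the controller's free parameters with CMA-ES.
#
# The search runs in a normalized box: every free parameter is scaled by
# its bounds to [0, 1]; the initial step size of 0.1 therefore equals the
# documented "10% of the bound range" initialization.  For high-dimensional
# configurations (n > 100, e.g. the 551-parameter default) the covariance
# is restricted to its diagonal (sep-CMA-ES) with the standard accelerated
# learning rate -- with a few thousand evaluations a full covariance could
# not be learned anyway.

#' Encode a controller configuration as a parameter vector
#'
#' @param config An `s2w_controller`.
#' @return An `s2w_parameter_vector`: list with `names`, `values`, `std`,
#'   `min`, `max` of the free parameters.
#' @export
encode_parameters <- function(config) {
  p <- config$params[config$params$free, , drop = FALSE]
  structure(list(names = p$name, values = p$value, std = p$std,
                 min = p$min, max = p$max),
            class = "s2w_parameter_vector")
}

#' Decode a parameter vector into a controller configuration
#'
#' Values are clipped to their bounds; mirrored (shared) parameters are
#' synchronized.  `decode(encode(config))` reproduces the configuration.
#'
#' @param values Numeric vector (ordered as the template's free
#'   parameters) or an `s2w_parameter_vector`.
#' @param template An `s2w_controller` providing structure and bounds.
#' @return An `s2w_controller`.
#' @export
decode_parameters <- function(values, template) {
  if (inherits(values, "s2w_parameter_vector")) values <- values$values
  free_names <- template$params$name[template$params$free]
  if (length(values) != length(free_names)) {
    stop("parameter vector length ", length(values), ", expected ",
         length(free_names), call. = FALSE)
  }
  set_parameters(template, stats::setNames(values, free_names))
}

#' Evaluate one candidate parameter vector
#'
#' Shooting evaluation: decode, simulate the scenario, score with the total
#' objective.  Deterministic in (vector, scenario, engine settings).
#'
#' @param values Free-parameter values.
#' @param model An `s2w_model`.
#' @param scenario An `s2w_scenario`.
#' @param template Controller template.
#' @param corridor Optional precomputed corridor.
#' @return Scalar objective (Inf on simulation failure).
#' @export
evaluate_candidate <- function(values, model, scenario,
                               template = default_controller_config(),
                               corridor = NULL) {
  config <- decode_parameters(values, template)
  tryCatch({
    traj <- simulate_s2w(model, config, scenario)
    objective_report(traj, model, scenario, corridor)$total
  }, error = function(e) Inf)
}

#' CMA-ES minimizer
#'
#' Covariance matrix adaptation evolution strategy with box constraints
#' (candidates are clipped into the box before evaluation).  Full
#' covariance for n <= diag_threshold, diagonal (sep-CMA) above.
#'
#' @param fn Objective function of a numeric vector.
#' @param x0 Initial mean.
#' @param sigma0 Initial step size.
#' @param lower,upper Bounds (recycled).
#' @param lambda Population size.
#' @param generations Number of generations.
#' @param seed Random seed.
#' @param diag_threshold Dimension above which the diagonal model is used.
#' @param trace Print progress every `trace` generations (0 = silent).
#' @return List: `par` (best), `value`, `history` (data.frame with per-
#'   generation best / best-so-far / sigma), `evals`.
#' @export
cma_es <- function(fn, x0, sigma0 = 0.1, lower = 0, upper = 1,
                   lambda = 10, generations = 100, seed = 1,
                   diag_threshold = 100, trace = 0) {
  set.seed(seed)
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  use_diag <- n > diag_threshold
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cs <- (mueff + 2) / (n + mueff + 5)
  ds <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  if (use_diag) {  # sep-CMA accelerated learning rates
    c1 <- min(1, c1 * (n + 2) / 3)
    cmu <- min(1 - c1, cmu * (n + 2) / 3)
  }
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- pmin(pmax(x0, lower), upper)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  if (use_diag) {
    Cdiag <- rep(1, n)
  } else {
    C <- diag(n); B <- diag(n); D <- rep(1, n); eigen_age <- 0
  }
  best_val <- Inf; best_par <- xmean
  hist <- vector("list", generations)
  evals <- 0

  for (g in seq_len(generations)) {
    Z <- matrix(rnorm(n * lambda), n, lambda)
    if (use_diag) {
      Y <- Z * sqrt(Cdiag)
    } else {
      Y <- B %*% (D * Z)
    }
    X <- xmean + sigma * Y
    Xc <- pmin(pmax(X, lower), upper)
    f <- apply(Xc, 2, fn)
    evals <- evals + lambda
    if (all(!is.finite(f))) {
      stop("CMA-ES: all candidates failed to evaluate at generation ", g)
    }
    ord <- order(f)
    if (f[ord[1]] < best_val) {
      best_val <- f[ord[1]]; best_par <- Xc[, ord[1]]
    }
    sel <- ord[seq_len(mu)]
    ymean <- drop(Y[, sel, drop = FALSE] %*% w)
    xmean <- xmean + sigma * ymean
    xmean <- pmin(pmax(xmean, lower), upper)
    # step-size path
    if (use_diag) {
      zmean <- drop((Y[, sel, drop = FALSE] / sqrt(Cdiag)) %*% w)
    } else {
      zmean <- drop(Z[, sel, drop = FALSE] %*% w)
      zmean <- drop(B %*% zmean)
    }
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * zmean
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * g)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean
    if (use_diag) {
      rank_mu <- drop((Y[, sel, drop = FALSE]^2) %*% w)
      Cdiag <- (1 - c1 - cmu) * Cdiag + c1 * (pc^2 +
                 (1 - hsig) * cc * (2 - cc) * Cdiag) + cmu * rank_mu
      Cdiag <- pmax(Cdiag, 1e-12)
    } else {
      artmp <- Y[, sel, drop = FALSE]
      C <- (1 - c1 - cmu) * C +
        c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
        cmu * artmp %*% (w * t(artmp))
      eigen_age <- eigen_age + 1
      if (eigen_age > 1 / (c1 + cmu) / n / 10) {
        eigen_age <- 0
        C <- (C + t(C)) / 2
        eg <- eigen(C, symmetric = TRUE)
        D <- sqrt(pmax(eg$values, 1e-20))
        B <- eg$vectors
      }
    }
    sigma <- sigma * exp((cs / ds) *
      (sqrt(sum(ps^2)) / chiN - 1))
    sigma <- min(sigma, 1)
    hist[[g]] <- data.frame(gen = g, best = f[ord[1]],
                            median = stats::median(f[is.finite(f)]),
                            best_so_far = best_val, sigma = sigma)
    if (trace > 0 && g %% trace == 0) {
      message(sprintf("gen %4d  best %.4f  bsf %.4f  sigma %.3f",
                      g, f[ord[1]], best_val, sigma))
    }
  }
  list(par = best_par, value = best_val,
       history = do.call(rbind, hist), evals = evals)
}

#' Optimize the sit-to-walk controller
#'
#' Shooting-based CMA-ES optimization of the controller's free parameters
#' (population size 10 by default).  Supports several runs with a shared
#' initial mean and distinct seeds (run sequentially; candidate evaluation
#' order never affects results); the best run is returned.  A warm start
#' replaces the initial mean by a saved parameter file or vector.
#'
#' @param model An `s2w_model`.
#' @param scenario An `s2w_scenario`.
#' @param template Controller template (defines the search space).
#' @param generations CMA-ES generations per run.
#' @param lambda Population size.
#' @param runs Number of parallel (independent) runs.
#' @param seed Base seed; run k uses `seed + k - 1`.
#' @param warm_start NULL, a `.par` file path, or a named value vector.
#' @param log_file Optional per-generation CSV log path.
#' @param trace Progress printing interval (generations; 0 = silent).
#' @return List: `config` (best decoded controller), `values`, `objective`,
#'   `history` (with run and seed columns), `template`.
#' @export
optimize_controller <- function(model, scenario,
                                template = default_controller_config(),
                                generations = 100, lambda = 10, runs = 1,
                                seed = 1, warm_start = NULL,
                                log_file = NULL, trace = 0) {
  pv <- encode_parameters(template)
  rng <- pv$max - pv$min
  if (is.character(warm_start)) {
    template <- read_par_file(warm_start, template)
    pv <- encode_parameters(template)
  } else if (is.numeric(warm_start) && !is.null(names(warm_start))) {
    template <- set_parameters(template, warm_start)
    pv <- encode_parameters(template)
  }
  x0 <- (pv$values - pv$min) / rng
  corridor <- default_corridor(model, scenario)
  fn <- function(z) {
    evaluate_candidate(pv$min + z * rng, model, scenario, template, corridor)
  }
  best <- NULL
  histories <- list()
  for (r in seq_len(runs)) {
    res <- cma_es(fn, x0, sigma0 = 0.1, lower = 0, upper = 1,
                  lambda = lambda, generations = generations,
                  seed = seed + r - 1, trace = trace)
    res$history$run <- r
    res$history$seed <- seed + r - 1
    histories[[r]] <- res$history
    if (is.null(best) || res$value < best$value) best <- res
  }
  history <- do.call(rbind, histories)
  if (!is.null(log_file)) utils::write.csv(history, log_file,
                                           row.names = FALSE)
  values <- pv$min + best$par * rng
  names(values) <- pv$names
  list(config = decode_parameters(values, template), values = values,
       objective = best$value, history = history, template = template)
}
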