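unit_space <- function(k, names = letters[seq_len(k)]) {
  param_space(names = names, lower = rep(0, k), upper = rep(1, k))
}

test_that("the Saltelli design has N(2k+2) rows inside the bounds", {
  sp <- unit_space(1L)
  d <- saltelli_sample(sp, 8, seed = 1)
  expect_equal(nrow(d), 32L)         # 8 * (2*1 + 2)

  sp13 <- param_space()              # the 13 default process parameters
  expect_length(sp13$names, 13L)
  d13 <- saltelli_sample(sp13, 10, seed = 1)
  expect_equal(nrow(d13), 10L * 28L)
  for (j in seq_along(sp13$names)) {
    expect_true(all(d13[, j] >= sp13$lower[j] - 1e-12))
    expect_true(all(d13[, j] <= sp13$upper[j] + 1e-12))
  }
  # fraction-valued parameters stay within their logical caps
  expect_lte(max(d13[, "fe2_solid_ineq"]), 1)
  expect_lte(max(d13[, "mineral_aggregation_probability"]), 100)
  expect_error(saltelli_sample(sp, 0), "positive")
})

test_that("Sobol indices recover the variance shares of an additive model", {
  sp <- unit_space(2L)
  N <- 2048L
  d <- saltelli_sample(sp, N, seed = 7)
  y <- d[, 1] + 2 * d[, 2]
  res <- sobol_indices(y, sp, N, n_boot = 50L)
  # analytic shares: Var = (1 + 4)/12, S1 = (0.2, 0.8)
  expect_equal(unname(res$S1), c(0.2, 0.8), tolerance = 0.05)
  expect_equal(unname(res$ST), c(0.2, 0.8), tolerance = 0.05)
  expect_equal(sum(res$S1), 1, tolerance = 0.05)
  expect_equal(max(abs(res$ST - res$S1)), 0, tolerance = 0.05)
  # no interactions: the S2 network has no edges
  net <- interaction_network(res, threshold = 0.05)
  expect_equal(nrow(net$edges), 0L)
  expect_true(all(net$nodes$ratio >= 0 & net$nodes$ratio <= 1))
})

test_that("Sobol indices match the Ishigami closed form within CI", {
  a <- 7; b <- 0.1
  sp <- param_space(names = c("x1", "x2", "x3"),
                    lower = rep(-pi, 3), upper = rep(pi, 3))
  N <- 1024L
  d <- saltelli_sample(sp, N, seed = 11)
  y <- sin(d[, 1]) + a * sin(d[, 2])^2 + b * d[, 3]^4 * sin(d[, 1])
  res <- sobol_indices(y, sp, N, n_boot = 100L)
  # analytic variance decomposition, computed independently
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  V <- V1 + V2 + V13
  S1_true <- c(V1 / V, V2 / V, 0)
  ST_true <- c((V1 + V13) / V, V2 / V, V13 / V)
  for (i in 1:3) {
    expect_lt(abs(res$S1[i] - S1_true[i]), res$S1_conf[i] + 0.03)
    expect_lt(abs(res$ST[i] - ST_true[i]), res$ST_conf[i] + 0.03)
  }
  # the only second-order interaction is x1:x3
  expect_gt(res$S2["x1", "x3"], 0.1)
  expect_lt(abs(res$S2["x1", "x2"]), 0.1)
})

test_that("constant outputs give all-zero indices instead of 0/0", {
  sp <- unit_space(2L)
  d <- saltelli_sample(sp, 64, seed = 3)
  res <- sobol_indices(rep(4.2, nrow(d)), sp, 64, n_boot = 10L)
  expect_equal(unname(res$S1), c(0, 0))
  expect_equal(unname(res$ST), c(0, 0))
  expect_equal(res$variance, 0)
})

test_that("indices are invariant under affine rescaling of the output", {
  sp <- unit_space(3L)
  N <- 256L
  d <- saltelli_sample(sp, N, seed = 5)
  y <- d[, 1] * d[, 2] + 3 * d[, 3]
  r1 <- sobol_indices(y, sp, N, n_boot = 0L)
  r2 <- sobol_indices(100 - 7 * y, sp, N, n_boot = 0L)
  expect_equal(r1$S1, r2$S1, tolerance = 1e-9)
  expect_equal(r1$ST, r2$ST, tolerance = 1e-9)
  expect_equal(r1$S2, r2$S2, tolerance = 1e-9)
  expect_error(sobol_indices(y[-1], sp, N), "does not match")
})

test_that("batch evaluation applies row overrides deterministically", {
  sp <- param_space(names = c("contact_reduction_rate",
                              "contact_oxidation_rate"))
  d <- saltelli_sample(sp, 4, seed = 2)
  # extractor that just reads back a configured value: no RNG involved
  ex <- function(config, schedule, seed) config$contact_reduction_rate
  y <- evaluate_batch(d, ex, schedule = oxic_schedule(0, "anoxic"))
  expect_equal(y, unname(d[, "contact_reduction_rate"]))
  y2 <- evaluate_batch(d, ex, schedule = oxic_schedule(0, "anoxic"))
  expect_identical(y, y2)
  # failures surface as NA with a warning, not an abort
  ex_bad <- function(config, schedule, seed)
    if (config$contact_reduction_rate > 100) stop("boom") else 1
  msgs <- capture_warnings(
    yb <- evaluate_batch(d, ex_bad, schedule = oxic_schedule(0, "anoxic")))
  expect_true(any(grepl("failed", msgs)))
  expect_true(anyNA(yb))
})

test_that("sensitivity extractors summarise real (tiny) simulations", {
  fx <- make_fixture_world("minimal_cycle")
  v <- extractor_last_anoxic_rate(fx$config, fx$schedule, seed = 3)
  expect_true(is.finite(v) && v > 0)
  n <- extractor_final_np_count(fx$config, fx$schedule, seed = 3)
  expect_true(is.finite(n) && n >= 0)
})

test_that("interaction networks export nodes and thresholded edges", {
  sp <- unit_space(3L)
  N <- 512L
  d <- saltelli_sample(sp, N, seed = 9)
  y <- d[, 1] * d[, 2]        # pure interaction between a and b
  res <- sobol_indices(y, sp, N, n_boot = 0L)
  net <- interaction_network(res, threshold = 0.05)
  expect_equal(nrow(net$nodes), 3L)
  expect_true(nrow(net$edges) >= 1L)
  expect_true(any(net$edges$source == "a" & net$edges$target == "b"))
  f <- withr::local_tempfile(fileext = ".json")
  write_sobol_json(res, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(length(parsed$S1), 3L)
})
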