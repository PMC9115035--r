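test_that("reducer-bound particles dissociate strictly above the Fe2+ threshold", {
  expect_true(dissociate_from_reducer(29, 71, 0.7))
  expect_false(dissociate_from_reducer(30, 70, 0.7))   # exactly at threshold
  expect_false(dissociate_from_reducer(0, 100, 1.0))   # threshold 1: never
  expect_error(dissociate_from_reducer(0, 0), "> 0")
})

test_that("stochastic shedding matches the Normal-draw probabilities", {
  set.seed(77)
  n <- 4e4
  # at d = shedding diameter the release probability is exactly 1/2
  p_at <- mean(dissociate_from_oxidizer(rep(10, n), 10, 2))
  expect_lt(abs(p_at - 0.5), 0.01)
  # at d = threshold - 2 sd it is the standard Normal tail, ~0.0228
  p_low <- mean(dissociate_from_oxidizer(rep(6, n), 10, 2))
  expect_lt(abs(p_low - stats::pnorm(-2)), 0.005)
  # degenerate sd: deterministic threshold crossing
  expect_true(dissociate_from_oxidizer(10.1, 10, 0))
  expect_false(dissociate_from_oxidizer(9.9, 10, 0))
})

test_that("single-solid equilibration follows the closed-form decay", {
  # one bulk patch, A = 0, D = 1000: target 900, first transfer 18 units
  w <- bare_world(5L, fe2_equilibrium_rate = 0.02, fe2_solid_ineq = 0.9)
  set_block(w, 2, 2, 2, 2, 2, 2)
  p <- pid(w, 2, 2, 2)
  w$dissolved_fe2 <- 1000
  equilibrate(w)
  expect_equal(w$fe2_ads[p], 18)
  expect_equal(w$dissolved_fe2, 982)

  # residual deviation after n steps is (1 - rate)^n of the initial deviation
  for (n_steps in c(1L, 10L, 150L)) {
    w <- bare_world(5L, fe2_equilibrium_rate = 0.02, fe2_solid_ineq = 0.9)
    set_block(w, 2, 2, 2, 2, 2, 2)
    w$dissolved_fe2 <- 1000
    A_eq <- 900
    for (s in seq_len(n_steps)) equilibrate(w)
    residual <- (A_eq - w$fe2_ads[p]) / A_eq
    expect_equal(residual, (1 - 0.02)^n_steps, tolerance = 1e-9)
  }
  # a solid already at its equilibrium load is a fixed point
  w$fe2_ads[p] <- 900; w$dissolved_fe2 <- 100
  equilibrate(w)
  expect_equal(w$fe2_ads[p], 900)
})

test_that("equilibration conserves Fe2+ and never overdraws the pool", {
  set.seed(5)
  w <- bare_world(6L, fe2_equilibrium_rate = 0.3)
  set_block(w, 1, 3, 1, 3, 1, 2)
  w$fe2_ads[w$bulk_idx] <- stats::runif(length(w$bulk_idx), 0, 50)
  for (k in 1:12) add_np(w, fe3 = stats::runif(1, 0.1, 5),
                         fe2 = stats::runif(1, 0, 5))
  w$dissolved_fe2 <- 5
  tot0 <- total_iron(w)
  for (s in 1:30) {
    equilibrate(w)
    expect_gte(w$dissolved_fe2, 0)
    expect_true(all(w$fe2_ads >= 0))
    expect_equal(total_iron(w), tot0, tolerance = 1e-9 * tot0)
  }
})

test_that("nanoparticle loss removes only free particles into the ledger", {
  w <- bare_world(5L, np_loss_percentage = 100)
  f1 <- add_np(w, fe3 = 10)
  f2 <- add_np(w, fe3 = 20)
  b1 <- add_np(w, fe3 = 30, bound = 1L)
  b2 <- add_np(w, fe3 = 40, bound = -1L)
  tot0 <- total_iron(w)
  gone <- np_loss_step(w)
  expect_equal(gone, 2L)
  expect_false(any(w$np_alive[c(f1, f2)]))
  expect_true(all(w$np_alive[c(b1, b2)]))
  expect_equal(w$removed_iron, 30)
  expect_equal(total_iron(w), tot0)

  w2 <- bare_world(5L, np_loss_percentage = 0)
  add_np(w2, fe3 = 10)
  expect_equal(np_loss_step(w2), 0L)
  expect_equal(np_count(w2), 1L)
})

test_that("aging clock increments per tick and reduction resets it", {
  cfg <- world_config(grid_side = 9L, fe_patch_percentage = 0,
                      initial_number_fe3reducer = 1L,
                      initial_number_fe2oxidizer = 0L,
                      aging_enabled = TRUE, np_loss_percentage = 0,
                      mineral_aggregation_probability = 0,
                      np_attachment_threshold = 100,  # keep it unbound
                      max_ticks = 10L)
  w <- build_world(cfg, seed = 3)
  a <- add_np(w, fe3 = 100, x = 0.5, y = 0.5, z = 0.5)
  sch <- oxic_schedule(0, "anoxic")
  for (k in 1:10) advance_tick(w, sch)
  expect_equal(w$np_tsr[a], 10)
  # susceptibility stays in [0,1] and is monotone between reductions
  s <- aging_susceptibility(0:1000, cfg$aging_lag, cfg$aging_rate)
  expect_true(all(s >= 0 & s <= 1))
})
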