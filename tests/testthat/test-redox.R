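test_that("an attached reducer splits reduction 1:4 between contact and shuttles", {
  fx <- make_fixture_world("single_cluster")
  w <- build_world(fx$config, seed = 2)
  w$oxic <- FALSE
  attach_reducer(w, 1, w$bulk_idx[w$is_edge[w$bulk_idx]][1])
  rate <- w$cfg$contact_reduction_rate
  for (k in 1:5) {
    before <- w$cum_reduced
    b <- reduce_step(w, 1)
    expect_equal(b$contact, rate)
    expect_equal(b$shuttle, 4 * rate)
    expect_equal(b$np, 0)
    expect_equal(w$cum_reduced - before, 5 * rate)
  }
  # shuttle pathway carries exactly 80% of the total
  expect_equal(w$cum_shuttle_reduced / w$cum_reduced, 0.8)
})

test_that("unattached reducers with no mineral in range reduce nothing", {
  w <- bare_world(5L, initial_number_fe3reducer = 1L)
  w$oxic <- FALSE
  b <- reduce_step(w, 1)
  expect_equal(b$contact + b$np + b$shuttle, 0)
  expect_equal(w$cum_reduced, 0)
})

test_that("bound-nanoparticle reduction follows the MtrC occupancy formula", {
  w <- bare_world(9L, initial_number_fe3reducer = 1L, e_shuttle_range = 0)
  w$oxic <- FALSE
  cfg <- w$cfg   # ratio 100, rate 100, area 3.5e6
  # particle sized so its MtrC fraction is exactly 0.01
  d <- sqrt(0.01 * cfg$cell_surface_area)
  iron <- iron_of_d(cfg, d)
  a <- add_np(w, fe3 = iron, x = w$r_x, y = w$r_y, z = w$r_z, bound = 1L)
  b <- reduce_step(w, 1)
  expect_equal(b$np, 0.01 * 100 * 100)          # 100 units reduced
  expect_equal(b$capacity_charged, 1)           # charged at 1/ratio
  expect_equal(w$np_fe2[a], 100)
  expect_equal(w$np_fe3[a], iron - 100)
  expect_equal(w$np_tsr[a], -1)                 # clock reset pending increment
})

test_that("reduction capacity accounting never exceeds four contact rates", {
  set.seed(31)
  w <- bare_world(9L, initial_number_fe3reducer = 1L, e_shuttle_range = 0)
  w$oxic <- FALSE
  cfg <- w$cfg
  for (k in 1:60) {
    add_np(w, fe3 = iron_of_d(cfg, stats::runif(1, 50, 260)),
           x = w$r_x, y = w$r_y, z = w$r_z, bound = 1L)
  }
  b <- reduce_step(w, 1)
  cap <- 4 * cfg$contact_reduction_rate
  expect_lte(b$np / cfg$np_mineral_reduction_ratio + b$shuttle, cap + 1e-9)
  expect_gt(b$np, 0)
})

test_that("aging susceptibility throttles nanoparticle reduction only", {
  w <- bare_world(9L, initial_number_fe3reducer = 1L, e_shuttle_range = 0,
                  aging_enabled = TRUE)
  w$oxic <- FALSE
  cfg <- w$cfg
  d <- sqrt(0.01 * cfg$cell_surface_area)
  a <- add_np(w, fe3 = iron_of_d(cfg, d), x = w$r_x, y = w$r_y, z = w$r_z,
              bound = 1L)
  w$np_tsr[a] <- 300   # susceptibility 1 - 0.003*100 = 0.7
  b <- reduce_step(w, 1)
  expect_equal(b$np, 0.7 * 100)
})

test_that("shedding-mode oxidation grows 40 surface particles from the pool", {
  w <- bare_world(5L, initial_number_fe2oxidizer = 1L,
                  contact_oxidation_rate = 3600,
                  encrustation_mode = "shedding")
  w$oxic <- TRUE
  w$dissolved_fe2 <- 3600
  used <- biotic_oxidation_step(w, 1)
  expect_equal(used, 3600)
  expect_equal(w$dissolved_fe2, 0)
  ids <- which(w$np_alive)
  expect_length(ids, 40L)
  expect_true(all(w$np_bound[ids] == -1L))
  expect_equal(w$np_fe3[ids], rep(90, 40))     # fe2_used/40 each, remainder 0
  expect_equal(w$cum_biotic_ox, 3600)
})

test_that("shedding remainder is spread over surface particles by footprint", {
  w <- bare_world(5L, initial_number_fe2oxidizer = 1L,
                  contact_oxidation_rate = 4000,
                  encrustation_mode = "shedding")
  w$oxic <- TRUE
  cfg <- w$cfg
  old_iron <- iron_of_d(cfg, 8)
  old <- integer(0)
  for (k in 1:30)
    old <- c(old, add_np(w, fe3 = old_iron, x = w$o_x, y = w$o_y, z = w$o_z,
                         bound = -1L))
  FF <- 4000
  w$dissolved_fe2 <- FF
  biotic_oxidation_step(w, 1)
  ids <- which(w$np_alive)
  expect_length(ids, 40L)
  new <- setdiff(ids, old)
  # independent arithmetic: 10 seeds of F/40; remainder 0.75F split prop. d^2
  seed <- FF / 40
  d2_old <- 8^2
  d2_new <- np_diameter_from_iron(seed, cfg$iron_per_cubicnm, cfg$unit_scale)^2
  tot <- 30 * d2_old + 10 * d2_new
  rem <- FF - 10 * seed
  expect_equal(w$np_fe3[old], rep(old_iron + rem * d2_old / tot, 30))
  expect_equal(w$np_fe3[new], rep(seed + rem * d2_new / tot, 10))
  expect_equal(sum(w$np_fe3[ids]), 30 * old_iron + FF, tolerance = 1e-12)
})

test_that("low-pH-mode oxidation feeds neighbourhood particles or makes one", {
  w <- bare_world(5L, initial_number_fe2oxidizer = 1L,
                  encrustation_mode = "low_ph", contact_oxidation_rate = 500)
  w$oxic <- TRUE
  w$dissolved_fe2 <- 200
  biotic_oxidation_step(w, 1)
  ids <- which(w$np_alive)
  expect_length(ids, 1L)             # no particle nearby -> one new free one
  expect_equal(w$np_bound[ids], 0L)
  expect_equal(w$np_fe3[ids], 200)
  expect_equal(ferrocycle:::patch_index_of(w, w$np_x[ids], w$np_y[ids],
                                           w$np_z[ids]),
               ferrocycle:::patch_index_of(w, w$o_x, w$o_y, w$o_z))
  # with neighbourhood particles the draw is split equally, none created
  w$dissolved_fe2 <- 300
  b <- add_np(w, fe3 = 50, x = w$o_x, y = w$o_y, z = w$o_z)
  biotic_oxidation_step(w, 1)
  expect_equal(np_count(w), 2L)
  expect_equal(w$np_fe3[b], 50 + 150)
  expect_equal(w$np_fe3[ids], 200 + 150)
})

test_that("biotic oxidation is a no-op on an empty pool and respects shares", {
  w <- bare_world(5L, initial_number_fe2oxidizer = 2L)
  w$oxic <- TRUE
  w$dissolved_fe2 <- 0
  expect_equal(biotic_oxidation_step(w, 1), 0)
  expect_equal(np_count(w), 0L)
  # equal shares: two oxidizers cannot overdraw the pool
  w$dissolved_fe2 <- 500
  ferrocycle:::biotic_oxidation_phase(w)
  expect_gte(w$dissolved_fe2, 0)
  expect_equal(w$cum_biotic_ox, 500, tolerance = 1e-12)
})

test_that("abiotic oxidation is first-order on every ferrous pool", {
  w <- bare_world(5L, abiotic_oxidation_ratio = 0.01)
  set_block(w, 2, 2, 2, 2, 2, 2)
  w$oxic <- TRUE
  w$dissolved_fe2 <- 1e4
  before <- total_iron(w)
  tot <- abiotic_oxidation_step(w)
  expect_equal(tot, 100)
  expect_equal(w$dissolved_fe2, 9900)
  # the dissolved share precipitates on the cluster edge
  expect_equal(sum(w$fe3) - sum(w$bulk) * w$cfg$bulk_fe3_per_patch, 100)
  expect_equal(total_iron(w), before)

  # nanoparticle valence swap keeps content (and diameter) constant
  a <- add_np(w, fe3 = 0.5, fe2 = 1000)
  d0 <- ferrocycle:::np_diameters(w, a)
  abiotic_oxidation_step(w)
  expect_equal(w$np_fe2[a], 990)
  expect_equal(w$np_fe3[a], 0.5 + 10)
  expect_equal(ferrocycle:::np_diameters(w, a), d0)
})

test_that("zero abiotic ratio leaves all pools untouched", {
  w <- bare_world(5L, abiotic_oxidation_ratio = 0)
  w$oxic <- TRUE
  w$dissolved_fe2 <- 1e4
  expect_equal(abiotic_oxidation_step(w), 0)
  expect_equal(w$dissolved_fe2, 1e4)
})

test_that("redox operations enforce the oxic/anoxic gating preconditions", {
  w <- bare_world(5L, initial_number_fe3reducer = 1L,
                  initial_number_fe2oxidizer = 1L)
  w$oxic <- TRUE
  expect_error(reduce_step(w, 1), "anoxic")
  w$oxic <- FALSE
  expect_error(biotic_oxidation_step(w, 1), "oxic")
  expect_error(abiotic_oxidation_step(w), "oxic")
})
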