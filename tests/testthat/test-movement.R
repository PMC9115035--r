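test_that("straight-line steps wrap toroidally and zero speed stands still", {
  w <- bare_world(21L)
  h <- c(1 / sqrt(3), 1 / sqrt(3), 1 / sqrt(3))
  mv <- ferrocycle:::advance_agents(w, 1.5, 2.5, 3.5, h[1], h[2], h[3],
                                    speed = 0)
  expect_equal(c(mv$x, mv$y, mv$z), c(1.5, 2.5, 3.5))
  # a 10 nm particle moves np_speed(10) = 45 patch lengths along its heading
  sp <- np_speed(10)
  mv <- ferrocycle:::advance_agents(w, 1.5, 2.5, 3.5, h[1], h[2], h[3],
                                    speed = sp)
  expect_equal(c(mv$x, mv$y, mv$z),
               (c(1.5, 2.5, 3.5) + sp * h) %% 21, tolerance = 1e-12)
})

test_that("core-bulk destinations are redirected to the nearest cluster edge", {
  # single-patch cluster: its only patch is the edge
  w <- bare_world(5L)
  set_block(w, 2, 2, 2, 2, 2, 2)
  expect_equal(redirect_to_cluster_edge(w, w$cluster_id[pid(w, 2, 2, 2)],
                                        c(0.5, 0.5, 0.5)),
               pid(w, 2, 2, 2))

  # 3x3x3 solid cluster: only the centre is core, redirect never lands there
  w <- bare_world(7L)
  set_block(w, 2, 4, 2, 4, 2, 4)
  centre <- pid(w, 3, 3, 3)
  expect_true(w$core[centre])
  expect_equal(sum(w$core), 1L)
  cl <- w$cluster_id[centre]
  for (s in 1:10) {
    from <- stats::runif(3, 0, 7)
    tgt <- redirect_to_cluster_edge(w, cl, from)
    expect_true(w$is_edge[tgt])
    expect_false(tgt == centre)
  }
  # an agent adjacent to a face is sent to that face
  tgt <- redirect_to_cluster_edge(w, cl, c(3.5, 3.5, 0.5))
  expect_equal(c(w$px[tgt], w$py[tgt]), c(3, 3))
  expect_true(w$pz[tgt] %in% c(2, 4))  # z=2 at wrapped distance, z=4 never
  expect_equal(w$pz[tgt], 2)
})

test_that("co-located free nanoparticles merge according to the probability", {
  w <- bare_world(5L, mineral_aggregation_probability = 100)
  a <- add_np(w, fe3 = 100, x = 1.5, y = 1.5, z = 1.5)
  b <- add_np(w, fe3 = 60, fe2 = 40, x = 1.2, y = 1.9, z = 1.4)
  before <- total_iron(w)
  aggregate_adhere(w, c(a, b))
  expect_equal(np_count(w), 1L)
  survivor <- which(w$np_alive)
  expect_equal(w$np_fe3[survivor] + w$np_fe2[survivor], 200)
  expect_equal(total_iron(w), before)

  # probability 0: never merges
  w <- bare_world(5L, mineral_aggregation_probability = 0)
  a <- add_np(w, fe3 = 100, x = 1.5, y = 1.5, z = 1.5)
  b <- add_np(w, fe3 = 100, x = 1.5, y = 1.6, z = 1.5)
  aggregate_adhere(w, c(a, b))
  expect_equal(np_count(w), 2L)
})

test_that("nanoparticle binding requires a ferric fraction above threshold", {
  w <- bare_world(5L, initial_number_fe3reducer = 1L,
                  np_attachment_threshold = 50)
  # particle with 40% Fe3+ on the reducer's patch: stays free
  a <- add_np(w, fe3 = 40, fe2 = 60, x = w$r_x, y = w$r_y, z = w$r_z)
  aggregate_adhere(w, a)
  expect_equal(w$np_bound[a], 0L)
  # 60% Fe3+: binds
  b <- add_np(w, fe3 = 60, fe2 = 40, x = w$r_x, y = w$r_y, z = w$r_z)
  aggregate_adhere(w, b)
  expect_equal(w$np_bound[b], 1L)
})

test_that("the MtrC occupancy cap blocks further nanoparticle binding", {
  w <- bare_world(5L, initial_number_fe3reducer = 1L)
  cfg <- w$cfg
  # one particle whose footprint almost fills the surface
  big <- iron_of_d(cfg, sqrt(cfg$cell_surface_area) * 0.99)
  a <- add_np(w, fe3 = big, x = w$r_x, y = w$r_y, z = w$r_z)
  aggregate_adhere(w, a)
  expect_equal(w$np_bound[a], 1L)
  b <- add_np(w, fe3 = iron_of_d(cfg, sqrt(cfg$cell_surface_area) * 0.3),
              x = w$r_x, y = w$r_y, z = w$r_z)
  aggregate_adhere(w, b)
  expect_equal(w$np_bound[b], 0L)
})

test_that("mineral adhesion needs a bulk patch below the passivation tolerance", {
  w <- bare_world(5L, initial_number_fe3reducer = 1L, fe2_ads_tolerance = 300)
  set_block(w, 2, 2, 2, 2, 2, 2)
  p <- pid(w, 2, 2, 2)
  w$r_x[1] <- 2.5; w$r_y[1] <- 2.5; w$r_z[1] <- 2.5
  expect_true(try_mineral_adhesion(w, 1, p))
  expect_equal(w$r_attached[1], p)
  # strict inequality at the tolerance
  w$r_attached[1] <- 0L
  w$fe2_ads[p] <- 300
  expect_false(try_mineral_adhesion(w, 1, p))
  # medium patches never bind
  w$r_attached[1] <- 0L
  expect_false(try_mineral_adhesion(w, 1, pid(w, 0, 0, 0)))
})

test_that("electrostatic detachment is immediate above tolerance, never below", {
  w <- bare_world(5L, initial_number_fe3reducer = 1L,
                  adhesion_mode = "electrostatic")
  set_block(w, 2, 2, 2, 2, 2, 2)
  p <- pid(w, 2, 2, 2)
  attach_reducer(w, 1, p)
  w$fe2_ads[p] <- 299
  expect_false(maybe_detach(w, 1))
  expect_equal(w$r_attached[1], p)
  w$fe2_ads[p] <- 301
  expect_true(maybe_detach(w, 1))
  expect_equal(w$r_attached[1], 0L)
})

test_that("biofilm detachment probability decays with residence time", {
  cfg <- world_config(adhesion_mode = "biofilm")
  p0 <- ferrocycle:::biofilm_detach_probability(cfg, 0, 0, oxic = FALSE)
  expect_equal(p0, cfg$biofilm_p0)
  p_late <- ferrocycle:::biofilm_detach_probability(cfg, 1200, 0, oxic = FALSE)
  expect_lt(p_late, 1e-4)  # 2^(-t/tau) -> 0
  # oxic conditions always raise the probability; neighbours lower it
  t <- c(0, 30, 60, 600)
  for (tt in t) {
    expect_gt(ferrocycle:::biofilm_detach_probability(cfg, tt, 0, TRUE),
              ferrocycle:::biofilm_detach_probability(cfg, tt, 0, FALSE))
    expect_lt(ferrocycle:::biofilm_detach_probability(cfg, tt, 3, FALSE),
              ferrocycle:::biofilm_detach_probability(cfg, tt, 0, FALSE))
  }
})

test_that("movement leaves nanoparticle count unchanged without aggregation", {
  cfg <- world_config(grid_side = 7L, fe_patch_percentage = 10,
                      initial_number_fe3reducer = 0L,
                      initial_number_fe2oxidizer = 0L,
                      initial_number_nanoparticle = 25L,
                      mineral_aggregation_probability = 0,
                      np_loss_percentage = 0, max_ticks = 30L)
  res <- run_simulation(cfg, oxic_schedule(0, "anoxic"), seed = 9)
  expect_equal(unique(res$np_count), 25)
})
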