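# Scenario experiments: phase summaries, replicate aggregation, and the
# calibration experiments used to validate the redox parameterisation.

#' Summarise a run by oxic/anoxic phase
#'
#' Splits a metrics series into the phases defined by the switching schedule
#' and reports per-phase mean rates (cumulative-counter increment divided by
#' phase duration, iron units per tick).
#'
#' @param series a metrics data.frame from [run_simulation()].
#' @param schedule the [oxic_schedule()] the run used.
#' @return data.frame with one row per phase: `phase`, `state`,
#'   `start`, `end`, `duration`, `reduction_rate`, `np_reduction_rate`,
#'   `biotic_ox_rate`, `abiotic_ox_rate`.
#' @export
summarize_phases <- function(series, schedule) {
  if (is.null(series) || !nrow(series)) stop("empty metrics series")
  stopifnot(inherits(schedule, "oxic_schedule"))
  last_tick <- max(series$tick)
  starts <- schedule$time_min[schedule$time_min < last_tick]
  ends <- c(schedule$time_min[-1], last_tick)
  ends <- pmin(ends[seq_along(starts)], last_tick)
  at <- function(col, t) series[[col]][match(t, series$tick)]
  dur <- ends - starts
  data.frame(
    phase = seq_along(starts),
    state = schedule$state[seq_along(starts)],
    start = starts,
    end = ends,
    duration = dur,
    reduction_rate = (at("cum_reduced", ends) - at("cum_reduced", starts)) / dur,
    np_reduction_rate = (at("cum_np_reduced", ends) -
                           at("cum_np_reduced", starts)) / dur,
    biotic_ox_rate = (at("cum_biotic_ox", ends) -
                        at("cum_biotic_ox", starts)) / dur,
    abiotic_ox_rate = (at("cum_abiotic_ox", ends) -
                         at("cum_abiotic_ox", starts)) / dur
  )
}

#' Biotic contribution to total oxidation
#'
#' Percentage of the iron oxidized during the run's oxic ticks that was
#' oxidized biotically: 100 * biotic / (biotic + abiotic), from the
#' cumulative counters of a metrics series.
#'
#' @param series a metrics data.frame from [run_simulation()].
#' @return percentage in \[0,100\] (NA if no oxidation occurred).
#' @export
biotic_oxidation_share <- function(series) {
  b <- series$cum_biotic_ox[nrow(series)] - series$cum_biotic_ox[1]
  a <- series$cum_abiotic_ox[nrow(series)] - series$cum_abiotic_ox[1]
  if (b + a <= 0) return(NA_real_)
  100 * b / (b + a)
}

#' Run replicate simulations and aggregate per tick
#'
#' Runs `n` simulations with seeds `base_seed, base_seed+1, ...` and returns
#' the element-wise mean and sample standard deviation of every metric.
#'
#' @param config a [world_config()].
#' @param schedule an [oxic_schedule()].
#' @param n number of replicates (>= 1).
#' @param base_seed first seed.
#' @return object of class `replicate_summary`: list with `mean` and `sd`
#'   data.frames (one row per tick), `n`, and `seeds`.
#' @export
run_replicates <- function(config, schedule, n = 20L, base_seed = 1L) {
  stopifnot(n >= 1)
  seeds <- base_seed + seq_len(n) - 1L
  s <- ss <- NULL
  for (sd_i in seeds) {
    m <- as.matrix(run_simulation(config, schedule, seed = sd_i))
    if (is.null(s)) {
      s <- m
      ss <- m^2
    } else {
      s <- s + m
      ss <- ss + m^2
    }
  }
  mu <- s / n
  if (n == 1L) {
    sdv <- mu * 0
  } else {
    v <- (ss - n * mu^2) / (n - 1)
    v[v < 0] <- 0        # guard tiny negative rounding
    sdv <- sqrt(v)
  }
  out <- list(mean = as.data.frame(mu), sd = as.data.frame(sdv),
              n = n, seeds = seeds)
  class(out) <- "replicate_summary"
  out
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("<replicate_summary> ", x$n, " replicates, ", nrow(x$mean),
      " ticks recorded\n", sep = "")
  invisible(x)
}

#' Mean nanoparticle diameter at release from the FeOB surface
#'
#' Running statistics over every shedding event of a world/run.
#'
#' @param world an `iron_world` after simulation (or the world slot of a run).
#' @return list with `n`, `mean` and `sd` of release diameters (nm).
#' @export
shedding_release_stats <- function(world) {
  n <- world$shed_n
  if (n == 0L) return(list(n = 0L, mean = NA_real_, sd = NA_real_))
  mu <- world$shed_sum / n
  v <- if (n > 1L) max(0, (world$shed_sumsq - n * mu^2) / (n - 1)) else 0
  list(n = n, mean = mu, sd = sqrt(v))
}

#' Shedding-size calibration experiment
#'
#' Measures the mean diameter at which surface nanoparticles are released
#' from the FeOB under growth-limited Fe2+ supply: a single oxidizer in a
#' mineral world whose Fe2+ reservoir is pre-adsorbed on the bulk patches, so
#' the dissolved pool is replenished only by the slow phase equilibration and
#' surface particles grow gradually toward the shedding size. Abiotic
#' oxidation and nanoparticle loss are disabled to isolate the biotic
#' precipitation pathway.
#'
#' @param seed RNG seed.
#' @param ticks run length (default 600).
#' @param fe2_reservoir total adsorbed Fe2+ placed on the bulk patches
#'   (iron units).
#' @return list with `n`, `mean`, `sd` of release diameters (nm).
#' @export
shedding_diameter_experiment <- function(seed = 1L, ticks = 600L,
                                         fe2_reservoir = 600) {
  cfg <- world_config(
    grid_side = 7L, fe_patch_percentage = 10, max_ticks = as.integer(ticks),
    initial_number_fe3reducer = 0L, initial_number_fe2oxidizer = 1L,
    abiotic_oxidation_ratio = 0, np_loss_percentage = 0,
    encrustation_mode = "shedding"
  )
  sch <- oxic_schedule(0, "oxic")
  w <- build_world(cfg, seed)
  nb <- length(w$bulk_idx)
  if (!nb) stop("fixture world has no bulk mineral")
  w$fe2_ads[w$bulk_idx] <- fe2_reservoir / nb
  run_simulation(cfg, sch, seed = seed, world = w)
  shedding_release_stats(w)
}

#' Test-fixture worlds
#'
#' Miniature configurations exercising the submodels quickly:
#' `empty` (no mineral, no agents — null dynamics), `single_cluster`
#' (5^3 lattice, one compact 27-patch cluster, one reducer — deterministic
#' contact + shuttle reduction), `minimal_cycle` (7^3 lattice, 2 reducers,
#' 2 oxidizers, a little dissolved Fe2+, one anoxic+oxic cycle — touches
#' every submodel).
#'
#' @param kind one of `"empty"`, `"single_cluster"`, `"minimal_cycle"`.
#' @return list with `config` and `schedule`.
#' @export
make_fixture_world <- function(kind = c("empty", "single_cluster",
                                        "minimal_cycle")) {
  kind <- match.arg(kind)
  switch(kind,
    empty = list(
      config = world_config(grid_side = 5L, fe_patch_percentage = 0,
                            initial_number_fe3reducer = 0L,
                            initial_number_fe2oxidizer = 0L,
                            initial_number_nanoparticle = 0L,
                            max_ticks = 20L),
      schedule = oxic_schedule(0, "anoxic")
    ),
    single_cluster = list(
      config = world_config(grid_side = 5L, fe_patch_percentage = 21.6,
                            fe_clustering = 1,
                            initial_number_fe3reducer = 1L,
                            initial_number_fe2oxidizer = 0L,
                            initial_number_nanoparticle = 0L,
                            bulk_fe3_per_patch = 2e6,  # ample Fe3+ reservoir
                            max_ticks = 50L),
      schedule = oxic_schedule(0, "anoxic")
    ),
    minimal_cycle = list(
      config = world_config(grid_side = 7L, fe_patch_percentage = 10,
                            initial_number_fe3reducer = 2L,
                            initial_number_fe2oxidizer = 2L,
                            initial_number_nanoparticle = 4L,
                            start_medium_fe2 = 1000,
                            max_ticks = 120L),
      schedule = oxic_schedule(c(0, 60), c("anoxic", "oxic"))
    )
  )
}
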