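#' World configuration
#'
#' Builds the full parameter set of the simulator. All defaults correspond to
#' the neutral-pH reference conditions; individual entries can be overridden
#' through `...`.
#'
#' Internal iron bookkeeping uses abstract "iron units" of `unit_scale` atoms
#' each (default 1e5 atoms/unit). Literature per-cell rates translate as
#' rate\[units/tick\] = rate\[atoms/min\] / unit_scale with one tick = one
#' minute, e.g. the contact reduction rate of 1e7 atoms/(cell min) becomes
#' 100 units/tick (see [derive_contact_reduction_rate()]).
#'
#' @param ... named parameter overrides; unknown names are an error.
#' @return A validated list of class `world_config`.
#'
#' @section Parameters:
#' \describe{
#'   \item{grid_side}{lattice edge length in patches (patch edge = 2 um).}
#'   \item{fe_patch_percentage}{percent of patches holding bulk iron mineral.}
#'   \item{fe_clustering}{bulk mineral clustering strength in \[0,1\];
#'     1 grows a single compact macroaggregate, 0 scatters seeds.}
#'   \item{initial_number_fe3reducer, initial_number_fe2oxidizer,
#'     initial_number_nanoparticle}{initial agent counts.}
#'   \item{start_medium_fe2}{initial dissolved Fe2+ pool (iron units).}
#'   \item{max_ticks}{simulation length in ticks (minutes).}
#'   \item{unit_scale}{atoms per internal iron unit.}
#'   \item{bulk_fe3_per_patch}{Fe3+ reservoir of each bulk patch (units).}
#'   \item{speed_fe2_oxidizer, speed_fe3_reducer}{baseline speeds,
#'     patches/tick.}
#'   \item{iron_per_cubicnm}{iron atoms per nm^3 of nanoparticle mineral.}
#'   \item{mineral_aggregation_probability}{percent chance that two co-located
#'     free nanoparticles aggregate.}
#'   \item{contact_reduction_rate}{Fe3+ reduced per attached FeRB per tick by
#'     direct contact (units).}
#'   \item{fe2_ads_tolerance}{adsorbed Fe2+ (units) above which FeRB will not
#'     adhere / will detach.}
#'   \item{np_mineral_reduction_ratio}{fold-faster reduction of nanoparticles
#'     relative to bulk mineral.}
#'   \item{abiotic_oxidation_ratio}{first-order fraction of each Fe2+ pool
#'     oxidized abiotically per oxic tick.}
#'   \item{np_attachment_threshold}{minimum Fe3+/total-iron percentage for a
#'     nanoparticle to adhere to an FeRB.}
#'   \item{np_dissociation_threshold}{Fe2+/total-iron fraction above which a
#'     bound nanoparticle leaves the FeRB.}
#'   \item{shedding_diameter}{diameter (nm) around which FeOB-surface
#'     nanoparticles are released.}
#'   \item{shedding_sd}{standard deviation (nm) of the stochastic shedding
#'     draw.}
#'   \item{fe2_equilibrium_rate}{per-tick fractional approach of adsorbed Fe2+
#'     toward phase equilibrium.}
#'   \item{e_shuttle_range}{electron-shuttle reduction range, patch lengths.}
#'   \item{fe2_solid_ineq}{equilibrium share of Fe2+ residing on solids.}
#'   \item{contact_oxidation_rate}{maximum Fe2+ oxidized per FeOB per tick
#'     (units).}
#'   \item{np_loss_percentage}{percent of free nanoparticles leaving the
#'     system per tick.}
#'   \item{adhesion_mode}{`"electrostatic"` or `"biofilm"` FeRB adhesion.}
#'   \item{encrustation_mode}{`"shedding"` or `"low_ph"` FeOB strategy.}
#'   \item{aging_enabled, aging_lag, aging_rate}{secondary-mineral aging: after
#'     `aging_lag` ticks without reduction a nanoparticle's reduction
#'     susceptibility decays linearly at `aging_rate` per tick.}
#'   \item{p_tumble}{baseline per-tick tumbling probability (tripled in the
#'     FeRB chemotactic state).}
#'   \item{chemo_persistence}{ticks the FeRB chemotactic state persists after
#'     mineral contact.}
#'   \item{biofilm_p0, biofilm_tau, biofilm_oxic_multiplier}{biofilm-mode
#'     detachment: probability p0 * 2^(-t_attached/tau) / (1 + n_neighbours),
#'     multiplied under oxic conditions.}
#'   \item{cell_surface_area}{FeRB cell surface (nm^2), reference area for
#'     MtrC occupancy.}
#' }
#' @export
#' @examples
#' cfg <- world_config(grid_side = 7, initial_number_fe3reducer = 2)
#' cfg$contact_reduction_rate
world_config <- function(...) {
  cfg <- default_config()
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown configuration parameter(s): ", paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
}

default_config <- function() {
  list(
    # world setup
    grid_side                       = 21L,
    fe_patch_percentage             = 10,
    fe_clustering                   = 0.8,
    initial_number_fe3reducer       = 50L,
    initial_number_fe2oxidizer      = 50L,
    initial_number_nanoparticle     = 0L,
    start_medium_fe2                = 0,
    max_ticks                       = 2880L,
    unit_scale                      = 1e5,
    bulk_fe3_per_patch              = 2e6,
    # movement
    speed_fe2_oxidizer              = 2,
    speed_fe3_reducer               = 2,
    p_tumble                        = 0.3,
    chemo_persistence               = 30L,
    biofilm_p0                      = 0.2,
    biofilm_tau                     = 60,
    biofilm_oxic_multiplier         = 2,
    # nanoparticle characteristics
    iron_per_cubicnm                = 25,
    cell_surface_area               = 3.5e6,
    # process parameters
    mineral_aggregation_probability = 100,
    contact_reduction_rate          = 100,
    fe2_ads_tolerance               = 300,
    np_mineral_reduction_ratio      = 100,
    abiotic_oxidation_ratio         = 0.01,
    np_attachment_threshold         = 50,
    np_dissociation_threshold       = 0.7,
    shedding_diameter               = 10,
    shedding_sd                     = 2,
    fe2_equilibrium_rate            = 0.02,
    e_shuttle_range                 = 10,
    fe2_solid_ineq                  = 0.9,
    contact_oxidation_rate          = 360,
    np_loss_percentage              = 0.2,
    # modes of action
    adhesion_mode                   = "electrostatic",
    encrustation_mode               = "shedding",
    aging_enabled                   = FALSE,
    aging_lag                       = 200,
    aging_rate                      = 0.003
  )
}

#' Validate a configuration list
#'
#' Checks ranges and enum values; returns the configuration blessed with class
#' `world_config` or signals a descriptive error.
#'
#' @param cfg a named list carrying every parameter of [world_config()].
#' @return the validated `world_config`.
#' @export
validate_config <- function(cfg) {
  need <- names(default_config())
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("configuration is missing parameter(s): ", paste(missing, collapse = ", "))

  num1 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", key, "' must be a single finite number")
    v
  }
  chk <- function(key, ok, what) {
    if (!ok) stop("parameter '", key, "' out of range: ", what)
  }

  nonneg <- c("fe_patch_percentage", "start_medium_fe2", "bulk_fe3_per_patch",
              "speed_fe2_oxidizer", "speed_fe3_reducer", "iron_per_cubicnm",
              "mineral_aggregation_probability", "contact_reduction_rate",
              "fe2_ads_tolerance", "np_mineral_reduction_ratio",
              "abiotic_oxidation_ratio", "np_attachment_threshold",
              "np_dissociation_threshold", "shedding_diameter", "shedding_sd",
              "fe2_equilibrium_rate", "e_shuttle_range", "fe2_solid_ineq",
              "contact_oxidation_rate", "np_loss_percentage", "aging_lag",
              "aging_rate", "cell_surface_area", "biofilm_p0", "biofilm_tau",
              "biofilm_oxic_multiplier", "p_tumble", "chemo_persistence",
              "unit_scale")
  for (key in nonneg) chk(key, num1(key) >= 0, "must be >= 0")

  for (key in c("fe_patch_percentage", "mineral_aggregation_probability",
                "np_attachment_threshold", "np_loss_percentage"))
    chk(key, num1(key) <= 100, "percentage must be <= 100")
  for (key in c("fe_clustering", "fe2_equilibrium_rate", "fe2_solid_ineq",
                "np_dissociation_threshold", "abiotic_oxidation_ratio",
                "p_tumble"))
    chk(key, num1(key) >= 0 && num1(key) <= 1, "fraction must lie in [0,1]")

  chk("grid_side", num1("grid_side") >= 3, "must be >= 3 patches")
  for (key in c("grid_side", "initial_number_fe3reducer",
                "initial_number_fe2oxidizer", "initial_number_nanoparticle",
                "max_ticks")) {
    v <- num1(key)
    chk(key, v >= 0 && v == floor(v), "must be a non-negative integer")
    cfg[[key]] <- as.integer(v)
  }
  chk("unit_scale", num1("unit_scale") > 0, "must be > 0")
  chk("iron_per_cubicnm", num1("iron_per_cubicnm") > 0, "must be > 0")
  chk("cell_surface_area", num1("cell_surface_area") > 0, "must be > 0")

  if (!cfg$adhesion_mode %in% c("electrostatic", "biofilm"))
    stop("adhesion_mode must be 'electrostatic' or 'biofilm'")
  if (!cfg$encrustation_mode %in% c("shedding", "low_ph"))
    stop("encrustation_mode must be 'shedding' or 'low_ph'")
  if (!is.logical(cfg$aging_enabled) || length(cfg$aging_enabled) != 1L ||
      is.na(cfg$aging_enabled))
    stop("aging_enabled must be TRUE or FALSE")

  structure(cfg, class = "world_config")
}

#' Apply named overrides to a configuration
#'
#' @param cfg a `world_config`.
#' @param overrides named list of parameter values (e.g. from [ph_preset()]).
#' @return the modified, re-validated `world_config`.
#' @export
modify_config <- function(cfg, overrides) {
  if (!length(overrides)) return(validate_config(cfg))
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown configuration parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  validate_config(cfg)
}

#' @export
print.world_config <- function(x, ...) {
  cat("<world_config>\n")
  cat(sprintf("  lattice      : %d^3 patches, %.1f%% bulk mineral (clustering %.2f)\n",
              x$grid_side, x$fe_patch_percentage, x$fe_clustering))
  cat(sprintf("  agents       : %d FeRB, %d FeOB, %d nanoparticles\n",
              x$initial_number_fe3reducer, x$initial_number_fe2oxidizer,
              x$initial_number_nanoparticle))
  cat(sprintf("  modes        : adhesion=%s, encrustation=%s, aging=%s\n",
              x$adhesion_mode, x$encrustation_mode,
              if (x$aging_enabled) "on" else "off"))
  cat(sprintf("  key rates    : reduction %g, oxidation %g units/tick; abiotic %g/tick\n",
              x$contact_reduction_rate, x$contact_oxidation_rate,
              x$abiotic_oxidation_ratio))
  invisible(x)
}

#' pH scenario presets
#'
#' Returns configuration overrides quantifying how pH shifts the three
#' pH-sensitive processes: abiotic Fe2+ oxidation (slow at pH 5, fast at
#' pH 7), FeRB adhesion strength on mineral surfaces (strong at pH 5), and
#' nanoparticle aggregation (maximal near the point of zero charge at
#' pH 7.8, strongly suppressed at pH 5).
#'
#' @param ph one of 5, 6, 7.
#' @param base configuration whose `fe2_ads_tolerance` the adhesion override is
#'   scaled from (default: package defaults).
#' @return named list of overrides for [modify_config()].
#' @export
#' @examples
#' cfg6 <- modify_config(world_config(), ph_preset(6))
ph_preset <- function(ph, base = world_config()) {
  if (length(ph) != 1L || !ph %in% c(5, 6, 7))
    stop("ph must be one of 5, 6, 7")
  tol <- base$fe2_ads_tolerance
  switch(as.character(ph),
    "5" = list(abiotic_oxidation_ratio = 0.001,
               mineral_aggregation_probability = 1,
               fe2_ads_tolerance = 10 * tol),
    "6" = list(abiotic_oxidation_ratio = 0.003,
               mineral_aggregation_probability = 10,
               fe2_ads_tolerance = tol),
    "7" = list(abiotic_oxidation_ratio = 0.01,
               mineral_aggregation_probability = 100,
               fe2_ads_tolerance = tol))
}

#' Mode-of-action combinations
#'
#' The four crossed combinations of FeRB adhesion strategy and FeOB
#' encrustation-prevention strategy: 1 = electrostatic + shedding,
#' 2 = electrostatic + low pH, 3 = biofilm (polymeric) + shedding,
#' 4 = biofilm + low pH.
#'
#' @param k combination index in 1..4.
#' @return named list with `adhesion_mode` and `encrustation_mode`.
#' @export
mode_combo <- function(k) {
  if (length(k) != 1L || !k %in% 1:4)
    stop("combination index must be one of 1, 2, 3, 4")
  list(
    adhesion_mode = c("electrostatic", "electrostatic", "biofilm", "biofilm")[k],
    encrustation_mode = c("shedding", "low_ph", "shedding", "low_ph")[k]
  )
}

#' Contact reduction rate from a whole-cell literature rate
#'
#' Whole-cell Fe3+ reduction rates measured in shuttle-permissive cultures
#' include the electron-shuttle pathway, which carries a fraction
#' `shuttle_share` (~80%) of the flux. The contact-only rate is the remainder.
#'
#' @param total_rate whole-cell reduction rate, atoms/(cell min).
#' @param shuttle_share fraction of flux via electron shuttles (default 0.8).
#' @param unit_scale atoms per iron unit; if supplied, the result is converted
#'   to units/tick. Default `NULL` returns atoms/(cell min).
#' @return contact reduction rate.
#' @export
#' @examples
#' derive_contact_reduction_rate(5e7)               # 1e7 atoms/(cell min)
#' derive_contact_reduction_rate(5e7, unit_scale = 1e5)  # 100 units/tick
derive_contact_reduction_rate <- function(total_rate, shuttle_share = 0.8,
                                          unit_scale = NULL) {
  stopifnot(total_rate >= 0, shuttle_share >= 0, shuttle_share < 1)
  rate <- total_rate * (1 - shuttle_share)
  if (!is.null(unit_scale)) rate <- rate / unit_scale
  rate
}

#' Calibrate the Fe2+ equilibration rate
#'
#' Finds the smallest rate on a grid (default two-decimal grid) for which the
#' residual deviation from phase equilibrium after `ticks` one-minute steps
#' drops below `target`. For a single solid pool the residual after n steps is
#' (1 - rate)^n of the initial deviation, so the search uses that closed form;
#' a full equilibration run reproduces it (see tests).
#'
#' @param ticks equilibration horizon in ticks (default 150, i.e. 2.5 h).
#' @param target residual fraction to undercut (default 0.05).
#' @param grid candidate rates, default `seq(0.01, 1, by = 0.01)`.
#' @return the smallest qualifying rate.
#' @export
#' @examples
#' calibrate_equilibrium_rate()  # 0.02
calibrate_equilibrium_rate <- function(ticks = 150L, target = 0.05,
                                       grid = seq(0.01, 1, by = 0.01)) {
  stopifnot(ticks >= 1, target > 0, all(grid > 0 & grid <= 1))
  residual <- (1 - grid)^ticks
  ok <- which(residual < target)
  if (!length(ok)) stop("no rate on the grid meets the residual target")
  grid[min(ok)]
}
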