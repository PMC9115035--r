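#' Nanoparticle diameter from iron content
#'
#' Nanoparticles are spheres of constant mineral density: a particle holding
#' `total_iron` internal units contains `total_iron * unit_scale` iron atoms
#' occupying `atoms / iron_per_cubicnm` nm^3, hence
#' d = (6 V / pi)^(1/3).
#'
#' @param total_iron iron content in internal units (> 0), vectorised.
#' @param iron_per_cubicnm iron atoms per nm^3 of mineral.
#' @param unit_scale atoms per internal iron unit.
#' @return diameter in nm.
#' @seealso [np_iron_from_diameter()] for the exact inverse.
#' @export
#' @examples
#' np_diameter_from_iron(13090, 25, 1)  # 10 nm sphere at 25 atoms/nm^3
np_diameter_from_iron <- function(total_iron, iron_per_cubicnm, unit_scale = 1) {
  if (any(total_iron <= 0)) stop("total_iron must be > 0")
  if (iron_per_cubicnm <= 0 || unit_scale <= 0)
    stop("iron_per_cubicnm and unit_scale must be > 0")
  (6 * total_iron * unit_scale / (pi * iron_per_cubicnm))^(1 / 3)
}

#' Iron content of a nanoparticle of given diameter
#'
#' @param diameter nm, > 0 (vectorised).
#' @inheritParams np_diameter_from_iron
#' @return iron content in internal units.
#' @export
np_iron_from_diameter <- function(diameter, iron_per_cubicnm, unit_scale = 1) {
  if (any(diameter <= 0)) stop("diameter must be > 0")
  if (iron_per_cubicnm <= 0 || unit_scale <= 0)
    stop("iron_per_cubicnm and unit_scale must be > 0")
  pi / 6 * diameter^3 * iron_per_cubicnm / unit_scale
}

#' Diffusive speed of a nanoparticle
#'
#' Speed declines linearly with diameter and is floored at one patch length
#' per tick: max(50 - 0.5 d, 1).
#'
#' @param diameter nm, > 0 (vectorised).
#' @return speed in patch lengths per tick.
#' @export
np_speed <- function(diameter) {
  if (any(diameter <= 0)) stop("diameter must be > 0")
  pmax(50 - 0.5 * diameter, 1)
}

#' Ferric iron fraction of a particle
#'
#' @param fe3,fe2 iron contents (units), vectorised; `fe3 + fe2` must be > 0.
#' @return fe3 / (fe3 + fe2) in \[0,1\].
#' @export
fe3_fraction <- function(fe3, fe2) {
  tot <- fe3 + fe2
  if (any(tot <= 0)) stop("particle iron content must be > 0")
  fe3 / tot
}

#' MtrC occupancy of a bound nanoparticle
#'
#' The ~10,000 outer-membrane MtrC cytochromes are assumed uniformly spread
#' over the FeRB surface; a bound particle of diameter d masks a squared-
#' diameter footprint, occupying `d^2 / cell_surface_area * 10000` MtrC,
#' i.e. a fraction `d^2 / cell_surface_area` of the cell's reduction
#' machinery.
#'
#' @param diameter nm (vectorised).
#' @param cell_surface_area nm^2.
#' @return list with `occupied` (MtrC count) and `fraction` (of total MtrC).
#' @export
#' @examples
#' mtrc_occupancy(10, 3.5e6)$fraction  # ~2.86e-5
mtrc_occupancy <- function(diameter, cell_surface_area) {
  if (any(diameter <= 0)) stop("diameter must be > 0")
  if (cell_surface_area <= 0) stop("cell_surface_area must be > 0")
  frac <- diameter^2 / cell_surface_area
  list(occupied = frac * 10000, fraction = frac)
}

#' Aging susceptibility of a nanoparticle
#'
#' Secondary-mineral formation: after `lag` ticks without being reduced, a
#' particle's reduction susceptibility decays linearly at `rate` per tick,
#' clamped to \[0,1\]. A reduction event resets the clock (susceptibility 1).
#'
#' @param ticks_since_reduction ticks since the last reduction (vectorised).
#' @param lag lag ticks before decay starts.
#' @param rate susceptibility loss per tick beyond the lag.
#' @return susceptibility in \[0,1\].
#' @export
#' @examples
#' aging_susceptibility(c(200, 300, 600), lag = 200, rate = 0.003)
aging_susceptibility <- function(ticks_since_reduction, lag, rate) {
  pmin(1, pmax(0, 1 - rate * pmax(0, ticks_since_reduction - lag)))
}
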