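# Dissociation, Fe2+ phase equilibration, nanoparticle loss and the
# secondary-mineral aging clock.

#' Dissociation of a reducer-bound nanoparticle
#'
#' Surface passivation: a bound particle leaves the FeRB once its Fe2+
#' fraction exceeds `np_dissociation_threshold` (strictly).
#'
#' @param fe3,fe2 particle iron contents (units), vectorised.
#' @param threshold Fe2+/total-iron fraction (default 0.7).
#' @return logical: particle dissociates.
#' @export
dissociate_from_reducer <- function(fe3, fe2, threshold = 0.7) {
  tot <- fe3 + fe2
  if (any(tot <= 0)) stop("particle iron content must be > 0")
  fe2 / tot > threshold
}

#' Stochastic shedding of an oxidizer-surface nanoparticle
#'
#' A surface particle of diameter d is released when a draw from
#' Normal(mean = d, sd = `sd`) exceeds `shedding_diameter`; at
#' d = `shedding_diameter` the release probability is exactly 0.5, and in the
#' sd -> 0 limit shedding becomes deterministic at d > `shedding_diameter`.
#'
#' @param diameter particle diameter(s), nm.
#' @param shedding_diameter release threshold, nm.
#' @param sd standard deviation of the draw, nm (default 2).
#' @return logical: particle is shed (consumes one RNG draw per particle).
#' @export
dissociate_from_oxidizer <- function(diameter, shedding_diameter = 10, sd = 2) {
  stats::rnorm(length(diameter), mean = diameter, sd = sd) > shedding_diameter
}

dissociation_step <- function(w) {
  cfg <- w$cfg
  ids <- which(w$np_alive & w$np_bound > 0L)
  if (length(ids)) {
    off <- dissociate_from_reducer(w$np_fe3[ids], w$np_fe2[ids],
                                   cfg$np_dissociation_threshold)
    w$np_bound[ids[off]] <- 0L
  }
  ids <- which(w$np_alive & w$np_bound < 0L)
  if (length(ids)) {
    d <- np_diameters(w, ids)
    off <- dissociate_from_oxidizer(d, cfg$shedding_diameter, cfg$shedding_sd)
    if (any(off)) {
      w$np_bound[ids[off]] <- 0L
      rel <- d[off]
      w$shed_sum <- w$shed_sum + sum(rel)
      w$shed_sumsq <- w$shed_sumsq + sum(rel^2)
      w$shed_n <- w$shed_n + length(rel)
    }
  }
  invisible(w)
}

#' Equilibrate Fe2+ between solids and solution
#'
#' Adsorption equilibrium: at equilibrium a fraction `fe2_solid_ineq` of all
#' Fe2+ resides on solid surfaces (bulk mineral patches and nanoparticles),
#' partitioned among solids in proportion to their exposed surface, taken as
#' (iron content)^(2/3) (geometric area scaling, identical for a mineral
#' block and a spherical particle). Each tick a fraction
#' `fe2_equilibrium_rate` of every solid's deviation from its equilibrium
#' load is transferred toward equilibrium (solid -> solution or solution ->
#' solid), with solution-bound transfers scaled down if they would overdraw
#' the dissolved pool. For a single solid this reduces to the closed form:
#' the deviation decays as (1 - rate)^n.
#'
#' @param world an `iron_world`.
#' @return the world, invisibly.
#' @export
equilibrate <- function(world) {
  w <- world
  cfg <- w$cfg
  rate <- cfg$fe2_equilibrium_rate
  if (rate <= 0) return(invisible(w))

  bp <- w$bulk_idx
  np <- which(w$np_alive)
  n_b <- length(bp); n_n <- length(np)
  if (n_b + n_n == 0L) return(invisible(w))

  A <- c(w$fe2_ads[bp], w$np_fe2[np])
  wt <- c((w$fe3[bp] + w$fe2_ads[bp])^(2 / 3),
          (w$np_fe3[np] + w$np_fe2[np])^(2 / 3))
  swt <- sum(wt)
  if (swt <= 0) return(invisible(w))
  D <- w$dissolved_fe2
  Astar <- cfg$fe2_solid_ineq * (sum(A) + D) * wt / swt
  delta <- rate * (A - Astar)          # >0: solid -> solution
  out <- pmax(delta, 0)
  into <- pmax(-delta, 0)
  tot_in <- sum(into)
  avail <- D + sum(out)
  if (tot_in > avail && tot_in > 0) into <- into * (avail / tot_in)
  Anew <- A - out + into
  w$dissolved_fe2 <- D + sum(out) - sum(into)
  if (n_b) w$fe2_ads[bp] <- Anew[seq_len(n_b)]
  if (n_n) w$np_fe2[np] <- Anew[n_b + seq_len(n_n)]
  invisible(w)
}

#' Random loss of free nanoparticles
#'
#' Each free-floating nanoparticle leaves the system (sedimentation,
#' incorporation into bulk mineral) with probability
#' `np_loss_percentage/100` per tick; its iron accrues to the removed-iron
#' ledger so the global iron balance stays closed.
#'
#' @param world an `iron_world`.
#' @return invisibly, the number of particles removed.
#' @export
np_loss_step <- function(world) {
  w <- world
  p <- w$cfg$np_loss_percentage / 100
  if (p <= 0) return(invisible(0L))
  free <- which(w$np_alive & w$np_bound == 0L)
  if (!length(free)) return(invisible(0L))
  gone <- free[stats::runif(length(free)) < p]
  if (length(gone)) {
    w$removed_iron <- w$removed_iron + sum(w$np_fe3[gone] + w$np_fe2[gone])
    w$np_alive[gone] <- FALSE
  }
  invisible(length(gone))
}

# end-of-tick aging clock: every particle not reduced this tick ages by one
# tick (reduction and creation set the clock to -1 within the tick)
aging_clock_step <- function(w) {
  a <- which(w$np_alive)
  if (length(a)) w$np_tsr[a] <- w$np_tsr[a] + 1
  invisible(w)
}
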