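# Redox submodels. Reduction runs only under anoxic conditions; biotic and
# abiotic oxidation only under oxic conditions (gating enforced by the tick
# loop; the exported single-agent operations check the state themselves).

# bulk patches whose centres lie within e_shuttle_range patch lengths of the
# centre of `patch`; memoised per patch (the mineral layout is static)
shuttle_patches <- function(w, patch) {
  key <- as.character(patch)
  hit <- w$shuttle_cache[[key]]
  if (!is.null(hit)) return(hit)
  bp <- w$bulk_idx
  if (!length(bp)) {
    w$shuttle_cache[[key]] <- integer(0)
    return(integer(0))
  }
  d2 <- tor_dist2(w$px[patch] + 0.5, w$py[patch] + 0.5, w$pz[patch] + 0.5,
                  w$px[bp] + 0.5, w$py[bp] + 0.5, w$pz[bp] + 0.5, w$n)
  res <- bp[d2 <= w$cfg$e_shuttle_range^2]
  w$shuttle_cache[[key]] <- res
  res
}

#' One anoxic reduction step of a single reducer
#'
#' Executes the three reduction pathways in order:
#' \enumerate{
#' \item Contact: if attached, `contact_reduction_rate` of the patch's Fe3+
#'   (capped by availability) is moved to the patch's adsorbed Fe2+.
#' \item Bound nanoparticles: the remaining reduction capacity is set to four
#'   times the contact rate (the shared MtrC/electron-shuttle resource). Each
#'   bound particle with Fe3+ is reduced by
#'   `MtrC_fraction * np_mineral_reduction_ratio * contact_reduction_rate`
#'   times its aging susceptibility, capped by its Fe3+ content and by the
#'   remaining capacity; the reduced amount divided by the ratio is charged
#'   against the capacity, and the particle's aging clock resets.
#' \item Electron shuttles: the remaining capacity is split equally over the
#'   bulk patches within `e_shuttle_range`, each share capped by the patch's
#'   Fe3+ and deposited as adsorbed Fe2+.
#' }
#'
#' @param world an `iron_world` in the anoxic state.
#' @param i reducer index.
#' @param bound_ids ids of the reducer's bound nanoparticles holding Fe3+
#'   (computed from the world when `NULL`; the tick loop precomputes them).
#' @return invisibly, a list with `contact`, `np`, `shuttle` (iron units
#'   reduced by each pathway) and `capacity_charged`.
#' @export
reduce_step <- function(world, i, bound_ids = NULL) {
  w <- world
  if (w$oxic) stop("reduction requires anoxic conditions")
  cfg <- w$cfg
  rate <- cfg$contact_reduction_rate
  ratio <- cfg$np_mineral_reduction_ratio

  contact <- 0
  patch <- w$r_attached[i]
  if (patch > 0L) {
    contact <- min(rate, w$fe3[patch])
    w$fe3[patch] <- w$fe3[patch] - contact
    w$fe2_ads[patch] <- w$fe2_ads[patch] + contact
  }

  cap <- 4 * rate
  np_red <- 0
  ids <- if (is.null(bound_ids))
    which(w$np_alive & w$np_bound == i & w$np_fe3 > 0)
  else bound_ids
  if (length(ids) && cap > 0 && ratio > 0) {
    d <- np_diameters(w, ids)
    susc <- if (cfg$aging_enabled)
      aging_susceptibility(w$np_tsr[ids], cfg$aging_lag, cfg$aging_rate)
    else 1
    pot <- pmin(d^2 / cfg$cell_surface_area * ratio * rate * susc,
                w$np_fe3[ids])
    charge <- cumsum(pot / ratio)
    x <- pot
    over <- charge > cap
    if (any(over)) {
      k <- which(over)[1]
      prev <- if (k > 1L) charge[k - 1L] else 0
      x[k] <- max(0, (cap - prev) * ratio)
      if (k < length(x)) x[(k + 1L):length(x)] <- 0
    }
    w$np_fe3[ids] <- w$np_fe3[ids] - x
    w$np_fe2[ids] <- w$np_fe2[ids] + x
    w$np_tsr[ids[x > 0]] <- -1   # clock resets; end-of-tick increment -> 0
    np_red <- sum(x)
    cap <- cap - np_red / ratio
  }

  shuttle <- 0
  if (cap > 0) {
    tgt <- shuttle_patches(w, if (patch > 0L) patch else
      patch_index_of(w, w$r_x[i], w$r_y[i], w$r_z[i]))
    if (length(tgt)) {
      share <- cap / length(tgt)
      x <- pmin(share, w$fe3[tgt])
      w$fe3[tgt] <- w$fe3[tgt] - x
      w$fe2_ads[tgt] <- w$fe2_ads[tgt] + x
      shuttle <- sum(x)
    }
  }

  w$cum_contact_reduced <- w$cum_contact_reduced + contact
  w$cum_np_reduced <- w$cum_np_reduced + np_red
  w$cum_shuttle_reduced <- w$cum_shuttle_reduced + shuttle
  w$cum_reduced <- w$cum_reduced + contact + np_red + shuttle
  invisible(list(contact = contact, np = np_red, shuttle = shuttle,
                 capacity_charged = np_red / max(ratio, 1e-300) + shuttle))
}

reduction_phase <- function(w) {
  nr <- length(w$r_x)
  if (!nr) return(invisible(w))
  ord <- if (nr > 1L) sample.int(nr) else 1L
  idx <- which(w$np_alive & w$np_bound > 0L & w$np_fe3 > 0)
  by_r <- if (length(idx)) split(idx, w$np_bound[idx]) else list()
  none <- integer(0)
  for (i in ord) {
    ids <- by_r[[as.character(i)]]
    reduce_step(w, i, bound_ids = if (is.null(ids)) none else ids)
  }
  invisible(w)
}

#' One oxic biotic-oxidation step of a single oxidizer
#'
#' The oxidizer draws `fe2_used = min(share, contact_oxidation_rate)` from the
#' dissolved Fe2+ pool (where `share` is its equal share of the pool) and
#' precipitates it as nanoparticle Fe3+ according to the encrustation mode:
#'
#' * shedding: the cell surface is topped up to 40 nanoparticles, each new one
#'   seeded with `fe2_used/40`; the remainder is distributed over all surface
#'   particles proportional to their squared diameter.
#' * low pH: if no free nanoparticle sits on the 27-patch neighbourhood, all
#'   of `fe2_used` forms one new free nanoparticle on the oxidizer's patch;
#'   otherwise it is split equally among those neighbourhood particles.
#'
#' @param world an `iron_world` in the oxic state.
#' @param i oxidizer index.
#' @param share the oxidizer's share of dissolved Fe2+ (default: equal split
#'   of the current pool).
#' @param surf_ids ids of the oxidizer's surface nanoparticles (computed from
#'   the world when `NULL`; the phase driver precomputes them).
#' @param pend internal accumulator for batched particle creation.
#' @return invisibly, the iron units oxidized.
#' @export
biotic_oxidation_step <- function(world, i,
                                  share = world$dissolved_fe2 /
                                    max(1L, length(world$o_x)),
                                  surf_ids = NULL, pend = NULL) {
  w <- world
  if (!w$oxic) stop("biotic oxidation requires oxic conditions")
  cfg <- w$cfg
  fe2_used <- min(share, cfg$contact_oxidation_rate, w$dissolved_fe2)
  if (fe2_used <= 0) return(invisible(0))
  w$dissolved_fe2 <- w$dissolved_fe2 - fe2_used
  w$cum_biotic_ox <- w$cum_biotic_ox + fe2_used
  flush <- is.null(pend)
  if (flush) pend <- new_pend()

  if (cfg$encrustation_mode == "shedding") {
    surf <- if (is.null(surf_ids)) which(w$np_alive & w$np_bound == -i)
      else surf_ids
    n_new <- max(0L, 40L - length(surf))
    spent <- 0
    new_fe3 <- numeric(0)
    if (n_new > 0L) {
      seed <- fe2_used / 40
      new_fe3 <- rep(seed, n_new)
      spent <- n_new * seed
    }
    rem <- fe2_used - spent
    if (rem > 0 && (length(surf) || n_new > 0L)) {
      wgt_old <- if (length(surf)) np_diameters(w, surf)^2 else numeric(0)
      wgt_new <- if (n_new > 0L)
        (6 * new_fe3 * cfg$unit_scale / (pi * cfg$iron_per_cubicnm))^(2 / 3)
      else numeric(0)
      tot <- sum(wgt_old) + sum(wgt_new)
      if (length(surf))
        w$np_fe3[surf] <- w$np_fe3[surf] + rem * wgt_old / tot
      new_fe3 <- new_fe3 + rem * wgt_new / tot
    }
    if (n_new > 0L)
      pend_push(pend, fe3 = new_fe3, x = rep(w$o_x[i], n_new),
                y = rep(w$o_y[i], n_new), z = rep(w$o_z[i], n_new),
                bound = rep(-i, n_new))
  } else {
    patch <- patch_index_of(w, w$o_x[i], w$o_y[i], w$o_z[i])
    nb27 <- c(patch, as.vector(neighbor_ids(w, patch)))
    free <- which(w$np_alive & w$np_bound == 0L)
    if (length(free)) {
      fp <- patch_index_of(w, w$np_x[free], w$np_y[free], w$np_z[free])
      free <- free[fp %in% nb27]
    }
    pfree <- which(pend$bound == 0L &
                     patch_index_of(w, pend$x, pend$y, pend$z) %in% nb27)
    k_nb <- length(free) + length(pfree)
    if (!k_nb) {
      pend_push(pend, fe3 = fe2_used, x = w$o_x[i], y = w$o_y[i],
                z = w$o_z[i], bound = 0L)
    } else {
      if (length(free)) w$np_fe3[free] <- w$np_fe3[free] + fe2_used / k_nb
      if (length(pfree)) pend$fe3[pfree] <- pend$fe3[pfree] + fe2_used / k_nb
    }
  }
  if (flush) pend_flush(w, pend)
  invisible(fe2_used)
}

new_pend <- function() {
  e <- new.env(parent = emptyenv())
  e$fe3 <- e$x <- e$y <- e$z <- numeric(0)
  e$bound <- integer(0)
  e
}

pend_push <- function(pend, fe3, x, y, z, bound) {
  pend$fe3 <- c(pend$fe3, fe3)
  pend$x <- c(pend$x, x); pend$y <- c(pend$y, y); pend$z <- c(pend$z, z)
  pend$bound <- c(pend$bound, as.integer(bound))
  invisible(pend)
}

pend_flush <- function(w, pend) {
  k <- length(pend$fe3)
  if (!k) return(invisible(w))
  h <- random_heading(k)
  np_add(w, fe3 = pend$fe3, fe2 = numeric(k),
         x = pend$x, y = pend$y, z = pend$z,
         hx = h[, 1], hy = h[, 2], hz = h[, 3],
         bound = pend$bound, tsr = rep(-1, k))
  invisible(w)
}

biotic_oxidation_phase <- function(w) {
  k <- length(w$o_x)
  if (!k) return(invisible(w))
  share <- w$dissolved_fe2 / k
  ord <- if (k > 1L) sample.int(k) else 1L
  idx <- which(w$np_alive & w$np_bound < 0L)
  by_o <- if (length(idx)) split(idx, -w$np_bound[idx]) else list()
  pend <- new_pend()
  none <- integer(0)
  for (i in ord) {
    ids <- by_o[[as.character(i)]]
    biotic_oxidation_step(w, i, share = share,
                          surf_ids = if (is.null(ids)) none else ids,
                          pend = pend)
  }
  pend_flush(w, pend)
  invisible(w)
}

#' One oxic abiotic-oxidation step
#'
#' First-order abiotic Fe2+ oxidation: a fraction `abiotic_oxidation_ratio`
#' of each of the three Fe2+ pools is oxidized per tick. Adsorbed Fe2+ turns
#' into the same patch's Fe3+; nanoparticle Fe2+ into the same particle's
#' Fe3+; the dissolved share precipitates as Fe3+ spread equally over the
#' edge patches of the bulk mineral (the accessible nucleation surface), or,
#' in a world without bulk mineral, as one new free nanoparticle.
#'
#' @param world an `iron_world` in the oxic state.
#' @return invisibly, the iron units oxidized.
#' @export
abiotic_oxidation_step <- function(world) {
  w <- world
  if (!w$oxic) stop("abiotic oxidation requires oxic conditions")
  rho <- w$cfg$abiotic_oxidation_ratio
  if (rho <= 0) return(invisible(0))

  amt_p <- rho * w$fe2_ads
  w$fe2_ads <- w$fe2_ads - amt_p
  w$fe3 <- w$fe3 + amt_p

  a <- which(w$np_alive)
  amt_np <- rho * w$np_fe2[a]
  w$np_fe2[a] <- w$np_fe2[a] - amt_np
  w$np_fe3[a] <- w$np_fe3[a] + amt_np

  d <- rho * w$dissolved_fe2
  if (d > 0) {
    w$dissolved_fe2 <- w$dissolved_fe2 - d
    edges <- which(w$is_edge)
    if (length(edges)) {
      w$fe3[edges] <- w$fe3[edges] + d / length(edges)
    } else {
      h <- random_heading(1L)
      medium <- which(!w$bulk)
      p <- medium[[sample.int(length(medium), 1L)]]
      np_add(w, fe3 = d, fe2 = 0,
             x = w$px[p] + stats::runif(1), y = w$py[p] + stats::runif(1),
             z = w$pz[p] + stats::runif(1),
             hx = h[1], hy = h[2], hz = h[3], bound = 0L, tsr = -1)
    }
  }
  tot <- sum(amt_p) + sum(amt_np) + d
  w$cum_abiotic_ox <- w$cum_abiotic_ox + tot
  invisible(tot)
}
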