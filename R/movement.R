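# Movement submodel. Processing order within a tick follows the framework
# contract: free nanoparticles first, then oxidizers, then reducers; the order
# of agents inside each group is reshuffled every tick.

#' Nearest edge patch of a mineral cluster
#'
#' Movement targets inside the core of a macroaggregate (bulk patches whose
#' entire Moore neighbourhood is bulk) are inaccessible; the destination is
#' redirected to the edge patch of the same cluster closest (wrapped
#' Euclidean distance) to the agent, ties broken by an RNG draw.
#'
#' @param world an `iron_world`.
#' @param cluster_id cluster id.
#' @param from numeric length-3 position the distance is measured from.
#' @return the patch id of the chosen edge patch.
#' @export
redirect_to_cluster_edge <- function(world, cluster_id, from) {
  edges <- world$edge_by_cluster[[as.character(cluster_id)]]
  if (is.null(edges) || !length(edges))
    stop("cluster ", cluster_id, " has no edge patches")
  d2 <- tor_dist2(from[1], from[2], from[3],
                  world$px[edges] + 0.5, world$py[edges] + 0.5,
                  world$pz[edges] + 0.5, world$n)
  best <- which(d2 == min(d2))
  if (length(best) > 1L) best <- best[[sample.int(length(best), 1L)]]
  edges[[best]]
}

# straight-line step with toroidal wrap; returns list(x, y, z, patch) after
# core-redirect. All arguments parallel vectors.
advance_agents <- function(w, x, y, z, hx, hy, hz, speed) {
  n <- w$n
  nx <- (x + speed * hx) %% n
  ny <- (y + speed * hy) %% n
  nz <- (z + speed * hz) %% n
  p <- patch_index_of(w, nx, ny, nz)
  hit <- which(w$core[p])
  for (i in hit) {
    tgt <- redirect_to_cluster_edge(w, w$cluster_id[p[i]], c(x[i], y[i], z[i]))
    nx[i] <- w$px[tgt] + 0.5
    ny[i] <- w$py[tgt] + 0.5
    nz[i] <- w$pz[tgt] + 0.5
    p[i] <- tgt
  }
  list(x = nx, y = ny, z = nz, patch = p)
}

# redraw headings for agents that tumble this tick
apply_tumbles <- function(w, hx, hy, hz, p_tumble) {
  k <- length(hx)
  if (!k) return(list(hx = hx, hy = hy, hz = hz))
  tum <- stats::runif(k) < p_tumble
  if (any(tum)) {
    h <- random_heading(sum(tum))
    hx[tum] <- h[, 1]; hy[tum] <- h[, 2]; hz[tum] <- h[, 3]
  }
  list(hx = hx, hy = hy, hz = hz)
}

# fraction of the reducer's MtrC masked by its bound nanoparticles
reducer_occupancy <- function(w, i) {
  ids <- which(w$np_alive & w$np_bound == i)
  if (!length(ids)) return(0)
  sum(np_diameters(w, ids)^2) / w$cfg$cell_surface_area
}

# occupancy of every reducer at once
all_reducer_occupancies <- function(w) {
  nr <- length(w$r_x)
  occ <- numeric(nr)
  ids <- which(w$np_alive & w$np_bound > 0L)
  if (length(ids)) {
    rs <- rowsum(np_diameters(w, ids)^2, w$np_bound[ids])
    occ[as.integer(rownames(rs))] <- rs[, 1] / w$cfg$cell_surface_area
  }
  occ
}

# Vectorised binding of pre-qualified nanoparticles (ferric fraction already
# above threshold) to reducer i, honouring the occupancy cap in processing
# order; returns the updated occupancy, leftover ids and bound ids.
bind_many <- function(w, i, ids, occ) {
  if (!length(ids)) return(list(occ = occ, left = ids, bound = integer(0)))
  cfg <- w$cfg
  tots <- w$np_fe3[ids] + w$np_fe2[ids]
  adds <- (6 * tots * cfg$unit_scale /
             (pi * cfg$iron_per_cubicnm))^(2 / 3) / cfg$cell_surface_area
  k <- sum(cumsum(adds) <= 1 - occ + 1e-12)
  if (k == 0L) return(list(occ = occ, left = ids, bound = integer(0)))
  b <- ids[seq_len(k)]
  w$np_bound[b] <- as.integer(i)
  w$np_x[b] <- w$r_x[i]; w$np_y[b] <- w$r_y[i]; w$np_z[b] <- w$r_z[i]
  list(occ = occ + sum(adds[seq_len(k)]),
       left = if (k < length(ids)) ids[-seq_len(k)] else integer(0),
       bound = b)
}

#' Attempt mineral adhesion of a reducer
#'
#' An unattached reducer standing on a bulk patch adheres if the adsorbed
#' Fe2+ of that patch is strictly below `fe2_ads_tolerance` (surface
#' passivation blocks adhesion).
#'
#' @param world an `iron_world`.
#' @param i reducer index.
#' @param patch patch id (default: the reducer's current patch).
#' @return logical, whether the reducer attached.
#' @export
try_mineral_adhesion <- function(world, i,
                                 patch = patch_index_of(world, world$r_x[i],
                                                        world$r_y[i],
                                                        world$r_z[i])) {
  if (world$r_attached[i] != 0L) return(FALSE)
  if (!world$bulk[patch]) return(FALSE)
  if (!(world$fe2_ads[patch] < world$cfg$fe2_ads_tolerance)) return(FALSE)
  world$r_attached[i] <- as.integer(patch)
  world$r_ticks_attached[i] <- 0
  TRUE
}

# detachment probability of an attached reducer under biofilm adhesion, given
# the passivation trigger already fired
biofilm_detach_probability <- function(cfg, ticks_attached, n_coclustered, oxic) {
  p <- cfg$biofilm_p0 * 2^(-ticks_attached / cfg$biofilm_tau) /
    (1 + n_coclustered)
  if (oxic) p <- p * cfg$biofilm_oxic_multiplier
  min(1, p)
}

#' Detachment check for an attached reducer
#'
#' Electrostatic mode releases the reducer immediately once adsorbed Fe2+ of
#' its patch exceeds the tolerance. Biofilm (polymeric) mode instead detaches
#' stochastically with probability
#' `p0 * 2^(-t_attached/tau) / (1 + n_neighbours)`, raised by a constant
#' factor under oxic conditions, where `n_neighbours` counts other reducers
#' attached to the same cluster within two patch lengths.
#'
#' @param world an `iron_world`.
#' @param i reducer index (must be attached).
#' @return logical, whether the reducer detached (state updated in place).
#' @export
maybe_detach <- function(world, i) {
  patch <- world$r_attached[i]
  if (patch == 0L) stop("reducer ", i, " is not attached")
  cfg <- world$cfg
  if (!(world$fe2_ads[patch] > cfg$fe2_ads_tolerance)) return(FALSE)
  detach <- if (cfg$adhesion_mode == "electrostatic") {
    TRUE
  } else {
    others <- which(world$r_attached > 0L)
    others <- others[others != i]
    n_co <- 0L
    if (length(others)) {
      same <- world$cluster_id[world$r_attached[others]] ==
        world$cluster_id[patch]
      others <- others[same]
      if (length(others)) {
        d2 <- tor_dist2(world$r_x[i], world$r_y[i], world$r_z[i],
                        world$r_x[others], world$r_y[others],
                        world$r_z[others], world$n)
        n_co <- sum(d2 <= 4)
      }
    }
    stats::runif(1) < biofilm_detach_probability(cfg, world$r_ticks_attached[i],
                                                 n_co, world$oxic)
  }
  if (detach) {
    world$r_attached[i] <- 0L
    world$r_ticks_attached[i] <- 0
  }
  detach
}

# --- per-tick movement submodel ------------------------------------------

move_free_nanoparticles <- function(w) {
  cfg <- w$cfg
  free <- which(w$np_alive & w$np_bound == 0L)
  if (!length(free)) return(invisible(w))
  ord <- if (length(free) > 1L) sample(free) else free

  h <- apply_tumbles(w, w$np_hx[ord], w$np_hy[ord], w$np_hz[ord], cfg$p_tumble)
  w$np_hx[ord] <- h$hx; w$np_hy[ord] <- h$hy; w$np_hz[ord] <- h$hz
  sp <- np_speed(np_diameters(w, ord))
  mv <- advance_agents(w, w$np_x[ord], w$np_y[ord], w$np_z[ord],
                       h$hx, h$hy, h$hz, sp)
  w$np_x[ord] <- mv$x; w$np_y[ord] <- mv$y; w$np_z[ord] <- mv$z
  aggregate_adhere(w, ord, mv$patch)
  invisible(w)
}

#' Contact handling of moved free nanoparticles
#'
#' After free nanoparticles move, each one interacts with co-located agents:
#' it adheres to a co-located reducer if its ferric fraction exceeds the
#' attachment threshold (and the reducer's MtrC occupancy cap allows), and
#' otherwise aggregates with co-located free nanoparticles with probability
#' `mineral_aggregation_probability/100`, the merged particle combining both
#' iron contents. Aggregation is resolved per patch: arrivals are processed
#' in their (random) movement order and each joins the patch's current
#' aggregate with the stated probability.
#'
#' @param world an `iron_world`.
#' @param np_ids nanoparticle ids that just moved, in processing order.
#' @param patches their landing patch ids (parallel to `np_ids`).
#' @return the world, invisibly.
#' @export
aggregate_adhere <- function(world, np_ids,
                             patches = patch_index_of(world, world$np_x[np_ids],
                                                      world$np_y[np_ids],
                                                      world$np_z[np_ids])) {
  w <- world
  cfg <- w$cfg
  if (!length(np_ids)) return(invisible(w))

  # 1) binding to reducers standing on the landing patch (threshold
  #    pre-filtered as a vector; per-reducer occupancy honoured in order)
  nr <- length(w$r_x)
  if (nr) {
    rpatch <- ifelse(w$r_attached > 0L, w$r_attached,
                     patch_index_of(w, w$r_x, w$r_y, w$r_z))
    tots <- w$np_fe3[np_ids] + w$np_fe2[np_ids]
    qual <- (w$np_fe3[np_ids] / tots > cfg$np_attachment_threshold / 100) &
      (patches %in% rpatch)
    bound_away <- logical(length(np_ids))
    if (any(qual)) {
      occ <- all_reducer_occupancies(w)
      qi <- which(qual)
      for (p in unique(patches[qi])) {
        here <- qi[patches[qi] == p]
        ids <- np_ids[here]
        rs <- which(rpatch == p)
        if (length(rs) > 1L) rs <- sample(rs)
        for (i in rs) {
          res <- bind_many(w, i, ids, occ[i])
          occ[i] <- res$occ
          bound_away[here[match(res$bound, np_ids[here])]] <- TRUE
          ids <- res$left
          if (!length(ids)) break
          here <- here[match(ids, np_ids[here])]
        }
      }
    }
    keep <- !bound_away
    np_ids <- np_ids[keep]
    patches <- patches[keep]
  }

  # 2) aggregation among the remaining free particles, per patch
  p <- cfg$mineral_aggregation_probability / 100
  if (p <= 0 || length(np_ids) < 2L) return(invisible(w))
  o <- order(patches)              # stable: preserves processing order in ties
  ids <- np_ids[o]; grp <- patches[o]
  head <- !duplicated(grp)
  if (all(head)) return(invisible(w))
  gidx <- cumsum(head)             # group number per row
  heads <- ids[head]
  merge <- !head & (stats::runif(length(ids)) < p)
  if (!any(merge)) return(invisible(w))
  tgt_grp <- gidx[merge]
  mids <- ids[merge]
  add_fe3 <- rowsum(w$np_fe3[mids], tgt_grp)
  add_fe2 <- rowsum(w$np_fe2[mids], tgt_grp)
  add_age <- rowsum(w$np_tsr[mids] * (w$np_fe3[mids] + w$np_fe2[mids]), tgt_grp)
  g <- as.integer(rownames(add_fe3))
  hids <- heads[g]
  h_iron <- w$np_fe3[hids] + w$np_fe2[hids]
  tot_iron <- h_iron + add_fe3[, 1] + add_fe2[, 1]
  # aggregate age: iron-weighted mean of the constituents' reduction clocks
  w$np_tsr[hids] <- (w$np_tsr[hids] * h_iron + add_age[, 1]) / tot_iron
  w$np_fe3[hids] <- w$np_fe3[hids] + add_fe3[, 1]
  w$np_fe2[hids] <- w$np_fe2[hids] + add_fe2[, 1]
  w$np_alive[mids] <- FALSE
  invisible(w)
}

move_oxidizers <- function(w) {
  cfg <- w$cfg
  k <- length(w$o_x)
  if (!k) return(invisible(w))
  ord <- if (k > 1L) sample.int(k) else 1L
  h <- apply_tumbles(w, w$o_hx[ord], w$o_hy[ord], w$o_hz[ord], cfg$p_tumble)
  w$o_hx[ord] <- h$hx; w$o_hy[ord] <- h$hy; w$o_hz[ord] <- h$hz
  mv <- advance_agents(w, w$o_x[ord], w$o_y[ord], w$o_z[ord],
                       h$hx, h$hy, h$hz, cfg$speed_fe2_oxidizer)
  w$o_x[ord] <- mv$x; w$o_y[ord] <- mv$y; w$o_z[ord] <- mv$z
  # surface nanoparticles ride along
  surf <- which(w$np_alive & w$np_bound < 0L)
  if (length(surf)) {
    j <- -w$np_bound[surf]
    w$np_x[surf] <- w$o_x[j]; w$np_y[surf] <- w$o_y[j]; w$np_z[surf] <- w$o_z[j]
  }
  invisible(w)
}

move_reducers <- function(w) {
  cfg <- w$cfg
  nr <- length(w$r_x)
  if (!nr) return(invisible(w))
  ord <- if (nr > 1L) sample.int(nr) else 1L

  free_ids <- which(w$np_alive & w$np_bound == 0L)
  free_patch <- if (length(free_ids))
    patch_index_of(w, w$np_x[free_ids], w$np_y[free_ids], w$np_z[free_ids])
  else integer(0)
  still_free <- rep(TRUE, length(free_ids))
  # sorted patch index -> binary-search lookup of co-located free particles
  fp_ord <- order(free_patch)
  fp_sorted <- free_patch[fp_ord]

  for (i in ord) {
    if (w$r_attached[i] != 0L) {
      w$r_ticks_attached[i] <- w$r_ticks_attached[i] + 1
      maybe_detach(w, i)
      next
    }
    # chemotactic state: renewed by mineral contact, then counts down
    patch <- patch_index_of(w, w$r_x[i], w$r_y[i], w$r_z[i])
    if (w$near_bulk[patch]) w$r_chemo[i] <- cfg$chemo_persistence
    chemo <- w$r_chemo[i] > 0
    p_t <- if (chemo) min(1, 3 * cfg$p_tumble) else cfg$p_tumble
    speed <- if (chemo) 2 * cfg$speed_fe3_reducer else cfg$speed_fe3_reducer
    if (stats::runif(1) < p_t) {
      h <- random_heading(1L)
      w$r_hx[i] <- h[1]; w$r_hy[i] <- h[2]; w$r_hz[i] <- h[3]
    }
    mv <- advance_agents(w, w$r_x[i], w$r_y[i], w$r_z[i],
                         w$r_hx[i], w$r_hy[i], w$r_hz[i], speed)
    w$r_x[i] <- mv$x; w$r_y[i] <- mv$y; w$r_z[i] <- mv$z
    if (chemo) w$r_chemo[i] <- w$r_chemo[i] - 1

    # capture co-located qualifying free nanoparticles, then try adhesion
    here <- mv$patch
    hi <- findInterval(here, fp_sorted)
    lo <- findInterval(here - 1L, fp_sorted) + 1L
    sel <- if (hi >= lo) fp_ord[lo:hi] else integer(0)
    if (length(sel)) sel <- sel[still_free[sel]]
    if (length(sel)) {
      if (length(sel) > 1L) sel <- sample(sel)
      ids <- free_ids[sel]
      tots <- w$np_fe3[ids] + w$np_fe2[ids]
      ok <- w$np_fe3[ids] / tots > cfg$np_attachment_threshold / 100
      if (any(ok)) {
        res <- bind_many(w, i, ids[ok], reducer_occupancy(w, i))
        still_free[sel[ok][match(res$bound, ids[ok])]] <- FALSE
      }
    }
    try_mineral_adhesion(w, i, here)
  }
  # nanoparticles bound to reducers ride along
  bnd <- which(w$np_alive & w$np_bound > 0L)
  if (length(bnd)) {
    j <- w$np_bound[bnd]
    w$np_x[bnd] <- w$r_x[j]; w$np_y[bnd] <- w$r_y[j]; w$np_z[bnd] <- w$r_z[j]
  }
  invisible(w)
}

movement_step <- function(w) {
  move_free_nanoparticles(w)
  move_oxidizers(w)
  move_reducers(w)
  invisible(w)
}
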