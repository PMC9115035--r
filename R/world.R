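# World state lives in an environment (reference semantics): submodels mutate
# it in place, which keeps the per-tick loop allocation-free where it matters.
# Patch fields are flat vectors indexed by patch id = 1 + x + n*y + n^2*z with
# integer coordinates in 0..n-1; agent and nanoparticle fields are parallel
# vectors. The lattice wraps toroidally in all three dimensions and
# neighbourhoods are 26-cell (Moore).

# offsets of the 26-cell Moore neighbourhood
.moore26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

patch_index <- function(n, fx, fy, fz) 1L + fx + n * fy + n * n * fz

patch_index_of <- function(w, x, y, z) {
  n <- w$n
  patch_index(n, floor(x) %% n, floor(y) %% n, floor(z) %% n)
}

# wrapped coordinate difference a - b on a ring of length n, result in [-n/2, n/2)
tor_delta <- function(a, b, n) {
  d <- (a - b) %% n
  d - n * (d >= n / 2)
}

tor_dist2 <- function(ax, ay, az, bx, by, bz, n) {
  tor_delta(ax, bx, n)^2 + tor_delta(ay, by, n)^2 + tor_delta(az, bz, n)^2
}

# patch ids of the 26 neighbours of each id in `idx` (matrix length(idx) x 26)
neighbor_ids <- function(w, idx) {
  n <- w$n
  fx <- w$px[idx]; fy <- w$py[idx]; fz <- w$pz[idx]
  m <- matrix(0L, length(idx), 26L)
  for (k in seq_len(26)) {
    m[, k] <- patch_index(n,
                          (fx + .moore26[k, 1]) %% n,
                          (fy + .moore26[k, 2]) %% n,
                          (fz + .moore26[k, 3]) %% n)
  }
  m
}

# recompute cluster ids, edge flags, core flags and lookup tables from w$bulk
rebuild_mineral_topology <- function(w) {
  npatch <- w$npatch
  bulk <- w$bulk
  w$bulk_idx <- which(bulk)
  w$cluster_id <- rep(NA_integer_, npatch)
  w$is_edge <- rep(FALSE, npatch)
  w$core <- rep(FALSE, npatch)
  w$near_bulk <- rep(FALSE, npatch)
  w$edge_by_cluster <- list()
  if (!length(w$bulk_idx)) {
    w$shuttle_cache <- new.env(parent = emptyenv())
    return(invisible(w))
  }

  nb <- neighbor_ids(w, w$bulk_idx)
  bulk_nb <- matrix(bulk[nb], nrow = nrow(nb))
  all_bulk_nb <- rowSums(bulk_nb) == 26L
  w$is_edge[w$bulk_idx] <- !all_bulk_nb
  w$core[w$bulk_idx] <- all_bulk_nb

  # any patch adjacent to bulk (chemotaxis trigger)
  near <- rep(FALSE, npatch)
  near[as.vector(nb)] <- TRUE
  w$near_bulk <- near

  # connected components over bulk patches (26-connectivity)
  comp <- rep(NA_integer_, npatch)
  pos <- integer(npatch); pos[w$bulk_idx] <- seq_along(w$bulk_idx)
  cid <- 0L
  for (start in w$bulk_idx) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      nbs <- nb[pos[cur], ]
      new <- nbs[bulk[nbs] & is.na(comp[nbs])]
      if (length(new)) {
        comp[new] <- cid
        queue <- c(queue, unique(new))
      }
    }
  }
  w$cluster_id <- comp
  edge_idx <- w$bulk_idx[w$is_edge[w$bulk_idx]]
  w$edge_by_cluster <- split(edge_idx, comp[edge_idx])
  w$n_clusters <- cid
  w$shuttle_cache <- new.env(parent = emptyenv())
  invisible(w)
}

place_bulk_patches <- function(w, n_bulk, clustering) {
  npatch <- w$npatch
  bulk <- rep(FALSE, npatch)
  if (n_bulk > 0) {
    n_seed <- min(n_bulk, max(1L, as.integer(round(n_bulk * (1 - clustering)))))
    seeds <- sample.int(npatch, n_seed)
    bulk[seeds] <- TRUE
    placed <- n_seed
    if (placed < n_bulk) {
      # candidate frontier: medium patches adjacent to bulk
      cand <- rep(FALSE, npatch)
      nb_seed <- neighbor_ids(w, seeds)
      cand[as.vector(nb_seed)] <- TRUE
      cand[bulk] <- FALSE
      while (placed < n_bulk) {
        pool <- which(cand)
        if (!length(pool)) stop("mineral growth frontier is empty")
        p <- pool[[sample.int(length(pool), 1L)]]
        bulk[p] <- TRUE
        cand[p] <- FALSE
        nbs <- neighbor_ids(w, p)
        nbs <- nbs[!bulk[nbs]]
        cand[nbs] <- TRUE
        placed <- placed + 1L
      }
    }
  }
  w$bulk <- bulk
  rebuild_mineral_topology(w)
}

random_heading <- function(k) {
  v <- matrix(stats::rnorm(3 * k), ncol = 3)
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm == 0] <- 1
  v / nrm
}

#' Build a simulation world
#'
#' Constructs the 3-D toroidal lattice, places the bulk-mineral
#' macroaggregates by clustered growth, seeds the agents uniformly at random
#' on medium patches, and initialises all iron pools.
#'
#' Bulk placement: `round(fe_patch_percentage/100 * grid_side^3)` patches are
#' converted to bulk mineral by choosing
#' `max(1, round(n_bulk * (1 - fe_clustering)))` seed patches uniformly at
#' random and repeatedly converting a uniformly chosen medium patch adjacent
#' to the growing mineral until the target count is reached. `fe_clustering`
#' of 1 therefore grows one compact macroaggregate, 0 scatters the mineral.
#'
#' @param config a [world_config()].
#' @param seed integer RNG seed; the run is fully reproducible given
#'   (config, schedule, seed).
#' @return an object of class `iron_world` (an environment).
#' @export
#' @examples
#' w <- build_world(world_config(grid_side = 7, initial_number_fe3reducer = 2,
#'                               initial_number_fe2oxidizer = 1), seed = 1)
#' w
build_world <- function(config, seed = 1L) {
  config <- validate_config(config)
  set.seed(as.integer(seed))
  n <- config$grid_side
  npatch <- n^3

  n_bulk <- as.integer(round(config$fe_patch_percentage / 100 * npatch))
  if (n_bulk > npatch)
    stop("configuration requests more bulk patches than patches exist")
  if (n_bulk == npatch)
    stop("configuration leaves zero medium patches")

  w <- new.env(parent = emptyenv())
  class(w) <- "iron_world"
  w$cfg <- config
  w$n <- n
  w$npatch <- npatch
  idx0 <- 0:(npatch - 1L)
  w$px <- idx0 %% n
  w$py <- (idx0 %/% n) %% n
  w$pz <- idx0 %/% (n * n)

  place_bulk_patches(w, n_bulk, config$fe_clustering)
  w$fe3 <- ifelse(w$bulk, config$bulk_fe3_per_patch, 0)
  w$fe2_ads <- numeric(npatch)

  medium_idx <- which(!w$bulk)

  place_on_medium <- function(k) {
    p <- medium_idx[sample.int(length(medium_idx), k, replace = TRUE)]
    cbind(w$px[p] + stats::runif(k), w$py[p] + stats::runif(k),
          w$pz[p] + stats::runif(k))
  }

  nr <- config$initial_number_fe3reducer
  pos <- place_on_medium(nr)
  w$r_x <- pos[, 1]; w$r_y <- pos[, 2]; w$r_z <- pos[, 3]
  h <- random_heading(nr)
  w$r_hx <- h[, 1]; w$r_hy <- h[, 2]; w$r_hz <- h[, 3]
  w$r_attached <- integer(nr)
  w$r_ticks_attached <- numeric(nr)
  w$r_chemo <- numeric(nr)

  no <- config$initial_number_fe2oxidizer
  pos <- place_on_medium(no)
  w$o_x <- pos[, 1]; w$o_y <- pos[, 2]; w$o_z <- pos[, 3]
  h <- random_heading(no)
  w$o_hx <- h[, 1]; w$o_hy <- h[, 2]; w$o_hz <- h[, 3]

  nn <- config$initial_number_nanoparticle
  init_iron <- np_iron_from_diameter(config$shedding_diameter,
                                     config$iron_per_cubicnm,
                                     config$unit_scale)
  w$np_alive <- logical(0)
  w$np_fe3 <- w$np_fe2 <- numeric(0)
  w$np_x <- w$np_y <- w$np_z <- numeric(0)
  w$np_hx <- w$np_hy <- w$np_hz <- numeric(0)
  w$np_bound <- integer(0)
  w$np_tsr <- numeric(0)
  w$np_n <- 0L
  if (nn > 0) {
    pos <- place_on_medium(nn)
    h <- random_heading(nn)
    np_add(w, fe3 = rep(init_iron, nn), fe2 = numeric(nn),
           x = pos[, 1], y = pos[, 2], z = pos[, 3],
           hx = h[, 1], hy = h[, 2], hz = h[, 3],
           bound = integer(nn))
  }

  w$dissolved_fe2 <- config$start_medium_fe2
  w$removed_iron <- 0
  w$cum_reduced <- 0
  w$cum_contact_reduced <- 0
  w$cum_shuttle_reduced <- 0
  w$cum_np_reduced <- 0
  w$cum_biotic_ox <- 0
  w$cum_abiotic_ox <- 0
  w$shed_sum <- 0
  w$shed_sumsq <- 0
  w$shed_n <- 0L
  w$tick <- 0L
  w$oxic <- FALSE
  w
}

.np_fields <- c("np_alive", "np_fe3", "np_fe2", "np_x", "np_y", "np_z",
                "np_hx", "np_hy", "np_hz", "np_bound", "np_tsr")

# append nanoparticles into preallocated storage; returns their indices.
# Storage doubles on demand; slots beyond w$np_n are dead (np_alive FALSE).
np_add <- function(w, fe3, fe2, x, y, z, hx, hy, hz, bound, tsr = NULL) {
  k <- length(fe3)
  if (!k) return(integer(0))
  n0 <- w$np_n
  cap <- length(w$np_alive)
  if (n0 + k > cap) {
    newcap <- max(2L * cap, n0 + k, 64L)
    pad <- newcap - cap
    w$np_alive <- c(w$np_alive, rep(FALSE, pad))
    for (f in setdiff(.np_fields, c("np_alive", "np_bound")))
      w[[f]] <- c(w[[f]], numeric(pad))
    w$np_bound <- c(w$np_bound, integer(pad))
  }
  ids <- n0 + seq_len(k)
  w$np_alive[ids] <- TRUE
  w$np_fe3[ids] <- fe3
  w$np_fe2[ids] <- fe2
  w$np_x[ids] <- x %% w$n; w$np_y[ids] <- y %% w$n; w$np_z[ids] <- z %% w$n
  w$np_hx[ids] <- hx; w$np_hy[ids] <- hy; w$np_hz[ids] <- hz
  w$np_bound[ids] <- as.integer(bound)
  w$np_tsr[ids] <- if (is.null(tsr)) 0 else tsr
  w$np_n <- n0 + k
  ids
}

# drop dead rows once they dominate storage
np_compact <- function(w) {
  n0 <- w$np_n
  if (n0 < 256L) return(invisible(w))
  used <- seq_len(n0)
  alive <- w$np_alive[used]
  n_alive <- sum(alive)
  if (n_alive > n0 / 2) return(invisible(w))
  keep <- used[alive]
  for (f in .np_fields) {
    v <- w[[f]][keep]
    length(v) <- length(w[[f]])    # keep capacity; pad tail
    v[is.na(v)] <- if (is.logical(v)) FALSE else 0
    w[[f]] <- v
  }
  w$np_n <- n_alive
  invisible(w)
}

np_diameters <- function(w, ids) {
  cfg <- w$cfg
  np_diameter_from_iron(w$np_fe3[ids] + w$np_fe2[ids],
                        cfg$iron_per_cubicnm, cfg$unit_scale)
}

#' Total iron inventory of a world
#'
#' Sums every pool: dissolved Fe2+, patch Fe3+ and adsorbed Fe2+, nanoparticle
#' Fe3+ and Fe2+, and the ledger of iron removed via nanoparticle loss. This
#' quantity is conserved over any run.
#'
#' @param world an `iron_world`.
#' @return total iron in internal units.
#' @export
total_iron <- function(world) {
  a <- which(world$np_alive)
  world$dissolved_fe2 + sum(world$fe3) + sum(world$fe2_ads) +
    sum(world$np_fe3[a]) + sum(world$np_fe2[a]) + world$removed_iron
}

#' Number of live nanoparticles
#' @param world an `iron_world`.
#' @param free_only count only free-floating particles.
#' @return integer count.
#' @export
np_count <- function(world, free_only = FALSE) {
  if (free_only) sum(world$np_alive & world$np_bound == 0L)
  else sum(world$np_alive)
}

#' Attach a reducer to a bulk patch
#'
#' Places reducer `i` at the centre of `patch` and marks it attached (used to
#' set up controlled reduction experiments; during simulation attachment
#' happens through movement).
#'
#' @param world an `iron_world`.
#' @param i reducer index.
#' @param patch patch id of a bulk patch.
#' @return the world, invisibly.
#' @export
attach_reducer <- function(world, i, patch) {
  if (!world$bulk[patch]) stop("patch ", patch, " is not bulk mineral")
  world$r_x[i] <- world$px[patch] + 0.5
  world$r_y[i] <- world$py[patch] + 0.5
  world$r_z[i] <- world$pz[patch] + 0.5
  world$r_attached[i] <- as.integer(patch)
  world$r_ticks_attached[i] <- 0
  invisible(world)
}

# replace the mineral layout wholesale (fixtures/tests); resets patch pools
set_bulk_patches <- function(world, bulk_idx) {
  bulk <- rep(FALSE, world$npatch)
  bulk[bulk_idx] <- TRUE
  if (all(bulk)) stop("configuration leaves zero medium patches")
  world$bulk <- bulk
  rebuild_mineral_topology(world)
  world$fe3 <- ifelse(bulk, world$cfg$bulk_fe3_per_patch, 0)
  world$fe2_ads <- numeric(world$npatch)
  invisible(world)
}

#' @export
print.iron_world <- function(x, ...) {
  cat("<iron_world> tick ", x$tick, " (", if (x$oxic) "oxic" else "anoxic",
      ")\n", sep = "")
  cat(sprintf("  lattice  : %d^3 = %d patches, %d bulk (%d cluster%s)\n",
              x$n, x$npatch, length(x$bulk_idx),
              if (is.null(x$n_clusters)) 0L else x$n_clusters,
              if (identical(x$n_clusters, 1L)) "" else "s"))
  cat(sprintf("  agents   : %d FeRB (%d attached), %d FeOB, %d nanoparticles\n",
              length(x$r_x), sum(x$r_attached > 0L), length(x$o_x),
              np_count(x)))
  cat(sprintf("  iron     : dissolved Fe2+ %.4g, adsorbed Fe2+ %.4g, bulk Fe3+ %.4g units\n",
              x$dissolved_fe2, sum(x$fe2_ads), sum(x$fe3)))
  cat(sprintf("  cumulative: reduced %.4g, biotic ox %.4g, abiotic ox %.4g units\n",
              x$cum_reduced, x$cum_biotic_ox, x$cum_abiotic_ox))
  invisible(x)
}
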