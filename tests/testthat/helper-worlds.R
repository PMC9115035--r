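# Small worlds and manipulation helpers shared across the suite.

# empty 5^3 (or n^3) world with no mineral and no agents
bare_world <- function(n = 5L, seed = 1L, ...) {
  cfg <- world_config(grid_side = as.integer(n), fe_patch_percentage = 0,
                      initial_number_fe3reducer = 0L,
                      initial_number_fe2oxidizer = 0L,
                      initial_number_nanoparticle = 0L, ...)
  build_world(cfg, seed = seed)
}

# patch id from 0-based coordinates
pid <- function(w, x, y, z) 1L + x + w$n * y + w$n^2 * z

# carve an axis-aligned block of bulk mineral into a world
set_block <- function(w, x0, x1, y0, y1, z0, z1) {
  g <- expand.grid(x = x0:x1, y = y0:y1, z = z0:z1)
  ferrocycle:::set_bulk_patches(w, pid(w, g$x, g$y, g$z))
  w
}

# append one nanoparticle with given contents/binding; returns its id
add_np <- function(w, fe3, fe2 = 0, x = 0.5, y = 0.5, z = 0.5, bound = 0L) {
  ferrocycle:::np_add(w, fe3 = fe3, fe2 = fe2, x = x, y = y, z = z,
                      hx = 1, hy = 0, hz = 0, bound = as.integer(bound))
}

# nanoparticle iron content equivalent to a given diameter under a config
iron_of_d <- function(cfg, d) {
  np_iron_from_diameter(d, cfg$iron_per_cubicnm, cfg$unit_scale)
}

max_rel_iron_drift <- function(series) {
  max(abs(series$total_iron - series$total_iron[1])) /
    max(series$total_iron[1], 1e-12)
}
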