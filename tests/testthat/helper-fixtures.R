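# Fixtures are built in code, never stored on disk.

# Small stack with hand-picked values: 2 rows x 3 cols, two layers.
tiny_stack <- function() {
  a <- matrix(c(
    1, 2, 3,
    4, 5, 6
  ), nrow = 2, byrow = TRUE)
  b <- matrix(c(
    10, 20, 30,
    40, 50, 60
  ), nrow = 2, byrow = TRUE)
  climate_stack(list(a = a, b = b), xmin = 0, ymax = 2, cell_size = 1)
}

# A niche_grid built directly from an occupancy matrix, for analytic
# identities (geometry fields consistent between calls with equal R).
manual_grid <- function(z, e = NULL) {
  z <- as.matrix(z)
  if (is.null(e)) e <- (z > 0) * 1
  env100 <- e > 0
  pos <- e[env100]
  env75 <- env100 & e >= stats::quantile(pos, 0.25, names = FALSE)
  structure(
    list(
      R = nrow(z), axis1 = seq_len(nrow(z)), axis2 = seq_len(ncol(z)),
      axis1_range = c(1, nrow(z)), axis2_range = c(1, ncol(z)),
      o = z, e = e, z = z,
      envelope_mask_100 = env100, envelope_mask_75 = env75,
      n_occurrences = sum(z > 0), region_id = "manual"
    ),
    class = "niche_grid"
  )
}

# A complete small synthetic world: landscape, species, background and
# occurrences, for tests that need a realistic but fast pipeline input.
small_world <- function(seed = 1, n_rows = 60, n_cols = 60, n_occ = 300,
                        n_bg = 2000, breadth = 0.75) {
  st <- make_landscape(landscape_spec("w", n_rows, n_cols, seed = seed))
  sp <- species_spec(c(0, 0, 0), rep(breadth, 3))
  suit <- suitability_surface(st, sp)
  list(
    stack = st, species = sp, suitability = suit,
    occ = sample_occurrences(suit, n_occ, seed = seed + 1),
    bg = sample_background(st, stack_bounds(st), n_bg, seed = seed + 2)
  )
}

# Niche grids for a conserved native/invaded pair under the default
# study conditions, scaled by `n_occ`/`n_bg`/grid size.
scenario_grids <- function(scen, seed, n_rows = 120, n_occ = 1000,
                           n_bg = 10000, R = 100) {
  sp <- species_spec(c(0, 0, 0), c(0.75, 0.75, 0.75))
  pair <- make_scenario_pair(
    landscape_spec("native", n_rows, n_rows, seed = seed + 11),
    landscape_spec("invaded", n_rows, n_rows, origin_lon = 90, seed = seed + 12),
    sp, scen, n_occ, n_occ,
    seed = seed + 20, altitude = FALSE
  )
  bg_n <- sample_background(
    pair$native$stack, stack_bounds(pair$native$stack), n_bg, seed + 31
  )
  bg_i <- sample_background(
    pair$invaded$stack, stack_bounds(pair$invaded$stack), n_bg, seed + 32
  )
  pca <- fit_pca(pair$native$stack, pair$invaded$stack, bg_n, bg_i)
  list(
    native = build_niche_grid(pca, pair$native$stack, bg_n,
      pair$native$occurrences,
      R = R, region_id = "native"
    ),
    invaded = build_niche_grid(pca, pair$invaded$stack, bg_i,
      pair$invaded$occurrences,
      R = R, region_id = "invaded"
    ),
    pair = pair, pca = pca, bg_n = bg_n, bg_i = bg_i
  )
}
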