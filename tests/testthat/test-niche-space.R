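test_that("PCA identities hold: variance fractions, orthonormal loadings, rank-1 case", {
  w1 <- small_world(seed = 1, n_rows = 40, n_cols = 40, n_occ = 50, n_bg = 1000)
  w2 <- small_world(seed = 2, n_rows = 40, n_cols = 40, n_occ = 50, n_bg = 1000)
  pca <- fit_pca(w1$stack, w2$stack, w1$bg, w2$bg)
  ev <- pca$explained_variance_fraction
  expect_equal(sum(ev), 1)
  expect_true(all(diff(ev) <= 1e-12))
  expect_equal(crossprod(pca$loadings), diag(ncol(pca$loadings)),
    ignore_attr = TRUE, tolerance = 1e-10
  )

  # two perfectly correlated variables: axis 1 carries all the variance
  st1 <- w1$stack
  st1 <- climate_stack(
    list(a = st1$layers$env1, b = 3 * st1$layers$env1 + 1),
    st1$xmin, st1$ymax, st1$cell_size
  )
  st2 <- w2$stack
  st2 <- climate_stack(
    list(a = st2$layers$env1, b = 3 * st2$layers$env1 + 1),
    st2$xmin, st2$ymax, st2$cell_size
  )
  pca1 <- fit_pca(st1, st2, w1$bg, w2$bg)
  expect_equal(pca1$explained_variance_fraction[1], 1, tolerance = 1e-10)
})

test_that("loadings recover a known two-factor construction up to sign", {
  # layers built from two orthogonal latent factors with unequal variance
  set.seed(11)
  f1 <- matrix(rnorm(1600, sd = 2), 40, 40)
  f2 <- matrix(rnorm(1600, sd = 1), 40, 40)
  st <- climate_stack(list(x = f1, y = f2), 0, 2, 0.05)
  bg <- sample_background(st, stack_bounds(st), 1500, seed = 3)
  pca <- fit_pca(st, st, bg, bg)
  # with standardization the rotation mixes the factors; check against an
  # independent prcomp on the same pooled sample
  env <- rbind(
    as.matrix(extract_env(st, bg$points$lon, bg$points$lat)),
    as.matrix(extract_env(st, bg$points$lon, bg$points$lat))
  )
  ref <- prcomp(env, center = TRUE, scale. = TRUE)
  expect_equal(abs(pca$loadings), abs(ref$rotation), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("pca_scores standardizes then rotates, and flags nodata points", {
  w1 <- small_world(seed = 3, n_rows = 30, n_cols = 30, n_occ = 30, n_bg = 600)
  w2 <- small_world(seed = 4, n_rows = 30, n_cols = 30, n_occ = 30, n_bg = 600)
  pca <- fit_pca(w1$stack, w2$stack, w1$bg, w2$bg)

  # hand oracle on three points: scale() then rotate with the stored loadings
  pts <- w1$occ[1:3, ]
  env <- as.matrix(extract_env(w1$stack, pts$lon, pts$lat))
  hand <- scale(env, center = pca$means, scale = pca$scales) %*% pca$loadings[, 1:2]
  got <- pca_scores(pca, w1$stack, pts)
  expect_equal(got$axis1, hand[, 1], ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(got$axis2, hand[, 2], ignore_attr = TRUE, tolerance = 1e-12)

  # pooled background projects to mean (0, 0)
  sc <- dplyr::bind_rows(
    pca_scores(pca, w1$stack, w1$bg$points),
    pca_scores(pca, w2$stack, w2$bg$points)
  )
  expect_equal(mean(sc$axis1), 0, tolerance = 1e-10)
  expect_equal(mean(sc$axis2), 0, tolerance = 1e-10)

  # projection is affine: differences depend only on environment differences
  d_env <- env[1, ] - env[2, ]
  d_sc <- as.numeric((d_env / pca$scales) %*% pca$loadings[, 1:2])
  expect_equal(
    c(got$axis1[1] - got$axis1[2], got$axis2[1] - got$axis2[2]),
    d_sc,
    tolerance = 1e-12
  )

  st_na <- w1$stack
  st_na$layers <- lapply(st_na$layers, function(m) {
    m[] <- NA_real_
    m
  })
  expect_error(pca_scores(pca, st_na, pts), "nodata")
})

test_that("niche grids satisfy their structural invariants", {
  g <- scenario_grids(scenario_spec("conserved"),
    seed = 1, n_rows = 50,
    n_occ = 200, n_bg = 2000, R = 60
  )
  for (grid in list(g$native, g$invaded)) {
    expect_true(all(grid$z >= 0))
    expect_true(all(grid$o >= 0))
    expect_true(all(grid$e >= 0))
    expect_true(all(grid$z[grid$e == 0] == 0))
    expect_equal(sum(grid$z / sum(grid$z)), 1)
    expect_true(all(grid$envelope_mask_100[grid$envelope_mask_75]))
  }
  # shared geometry across regions by construction
  expect_equal(g$native$axis1, g$invaded$axis1)
  expect_equal(g$native$axis2, g$invaded$axis2)

  expect_error(
    build_niche_grid(g$pca, g$pair$native$stack, g$bg_n,
      g$pair$native$occurrences[1:4, ],
      R = 60
    ),
    "at least 5"
  )
  expect_error(
    build_niche_grid(g$pca, g$pair$native$stack, g$bg_n,
      g$pair$native$occurrences,
      R = 10
    ),
    "at least 25"
  )
})

test_that("occupancy is flat for uniform use of a uniform background", {
  # occurrences drawn uniformly over the same cells as the background:
  # corrected occupancy should be approximately constant on the envelope
  st <- make_landscape(landscape_spec("u", 80, 80, seed = 21))
  unif <- suitability_map(
    matrix(1, 80, 80), st$xmin, st$ymax, st$cell_size
  )
  occ <- sample_occurrences(unif, 1000, seed = 22, dedup = FALSE)
  bg <- sample_background(st, stack_bounds(st), 8000, seed = 23)
  pca <- fit_pca(st, st, bg, bg)
  grid <- build_niche_grid(pca, st, bg, occ, R = 100)
  z75 <- grid$z[grid$envelope_mask_75]
  expect_lt(sd(z75) / mean(z75), 0.45)
})

test_that("a tight occurrence cluster peaks at its own niche position", {
  w <- small_world(seed = 31, n_rows = 50, n_cols = 50, n_occ = 50, n_bg = 3000)
  st <- w$stack
  # cluster: many records in a single cell neighbourhood
  target <- cell_center(st, 25, 25)
  # every record in one raster cell: a single point in niche space
  occ <- tibble::tibble(
    lon = target$lon + runif(30, -0.02, 0.02),
    lat = target$lat + runif(30, -0.02, 0.02),
    year = NA_integer_, source = "t"
  )
  pca <- fit_pca(st, st, w$bg, w$bg)
  grid <- build_niche_grid(pca, st, w$bg, occ, R = 80)
  peak <- which(grid$z == max(grid$z), arr.ind = TRUE)[1, ]
  centroid <- colMeans(pca_scores(pca, st, occ))
  step1 <- diff(grid$axis1[1:2])
  step2 <- diff(grid$axis2[1:2])
  expect_lt(abs(grid$axis1[peak[1]] - centroid[1]), 1.5 * step1)
  expect_lt(abs(grid$axis2[peak[2]] - centroid[2]), 1.5 * step2)
})
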