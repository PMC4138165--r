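test_that("landscape generation is deterministic and respects the correlation target", {
  spec <- landscape_spec("r", 50, 50,
    n_layers = 3, spatial_smoothing = 5,
    layer_correlation = 0, seed = 1
  )
  st1 <- make_landscape(spec)
  st2 <- make_landscape(spec)
  expect_identical(st1$layers, st2$layers)

  # target correlation 0: all pairwise |r| below 0.15
  v <- sapply(st1$layers, as.vector)
  cm <- cor(v)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.15)

  # a strong positive target is tracked within +/- 0.15
  st_hi <- make_landscape(landscape_spec("r", 50, 50,
    n_layers = 3,
    spatial_smoothing = 5, layer_correlation = 0.7, seed = 2
  ))
  cm_hi <- cor(sapply(st_hi$layers, as.vector))
  expect_true(all(abs(cm_hi[upper.tri(cm_hi)] - 0.7) < 0.15))
})

test_that("zero smoothing yields spatially white layers, smoothing adds autocorrelation", {
  neighbor_r <- function(m) cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))
  st0 <- make_landscape(landscape_spec("r", 60, 60,
    spatial_smoothing = 0,
    layer_correlation = 0, seed = 3
  ))
  # remove the deterministic gradient before measuring lag-1 correlation
  resid <- function(m) m - rowMeans(m) %o% rep(1, ncol(m))
  expect_lt(abs(neighbor_r(resid(st0$layers$env1))), 0.1)

  st5 <- make_landscape(landscape_spec("r", 60, 60,
    spatial_smoothing = 5,
    layer_correlation = 0, seed = 3
  ))
  expect_gt(neighbor_r(resid(st5$layers$env1)), 0.5)
})

test_that("landscape spec validation rejects degenerate dimensions", {
  expect_error(landscape_spec("r", 5, 50), "n_rows")
  expect_error(landscape_spec("r", 50, 50, n_layers = 1), "n_layers")
  expect_error(landscape_spec("r", 50, 50, layer_correlation = 1.2), "layer_correlation")
})

test_that("suitability surface matches the Gaussian closed form and propagates nodata", {
  st <- tiny_stack()
  sp <- species_spec(c(5, 50), c(1, 10), max_suitability = 0.8)
  suit <- suitability_surface(st, sp)
  # cell (2,2) holds exactly the niche center (a=5, b=50)
  expect_equal(suit$values[2, 2], 0.8)
  # cell (2,1): a=4 is 1 sd from 5, b=40 is 1 sd from 50
  expect_equal(suit$values[2, 1], 0.8 * exp(-1))
  # one axis 1 sd away, other at the optimum
  sp2 <- species_spec(c(4, 50), c(1, 10), max_suitability = 0.8)
  expect_equal(suitability_surface(st, sp2)$values[2, 2], 0.8 * exp(-0.5))

  na_stack <- climate_stack(
    list(a = matrix(NA_real_, 3, 3), b = matrix(NA_real_, 3, 3)),
    0, 3, 1
  )
  expect_true(all(is.na(suitability_surface(na_stack, sp)$values)))

  expect_error(
    suitability_surface(st, species_spec(c(1, 2, 3), c(1, 1, 1))),
    "layers"
  )
})

test_that("occurrence sampling is proportional to suitability and seeded", {
  # single positive cell: the draw is forced to its center
  v <- matrix(0, 3, 3)
  v[2, 3] <- 0.5
  suit <- suitability_map(v, xmin = 0, ymax = 3, cell_size = 1)
  occ <- sample_occurrences(suit, 1, seed = 1)
  expect_equal(occ$lon, 2.5)
  expect_equal(occ$lat, 1.5)

  # uniform suitability: empirical frequencies uniform within multinomial error
  unif <- suitability_map(matrix(1, 5, 5), 0, 5, 1)
  occ_u <- sample_occurrences(unif, 5000, seed = 2, dedup = FALSE)
  counts <- table(paste(occ_u$lon, occ_u$lat))
  expect_length(counts, 25)
  gof <- chisq.test(as.vector(counts))
  expect_gt(gof$p.value, 0.001)

  # deduplication cap is enforced with an informative error
  expect_error(sample_occurrences(suit, 2, seed = 1), "maximum")

  # reproducibility
  o1 <- sample_occurrences(unif, 20, seed = 7)
  o2 <- sample_occurrences(unif, 20, seed = 7)
  expect_identical(o1, o2)
})

test_that("scenario pairs encode the intended ground truth", {
  sp <- species_spec(c(0, 0, 0), c(0.75, 0.75, 0.75))
  mk <- function(scen) {
    make_scenario_pair(
      landscape_spec("n", 50, 50, seed = 1),
      landscape_spec("i", 50, 50, origin_lon = 90, seed = 2),
      sp, scen, 100, 100,
      seed = 5, altitude = FALSE
    )
  }
  cons <- mk(scenario_spec("conserved"))
  expect_identical(cons$native$species, cons$invaded$species)

  exp2 <- mk(scenario_spec("expanded", shift = c(1.5, 0, 0)))
  expect_equal(
    exp2$invaded$species$niche_center - exp2$native$species$niche_center,
    c(1.5, 0, 0)
  )

  unf <- mk(scenario_spec("unfilled", truncation_quantile = 0.5))
  for (v in c("env1", "env2", "env3")) {
    rng_n <- range(unf$native$stack$layers[[v]], na.rm = TRUE)
    rng_i <- range(unf$invaded$stack$layers[[v]], na.rm = TRUE)
    expect_gt(rng_i[1], rng_n[1])
    expect_lt(rng_i[2], rng_n[2])
  }

  expect_error(scenario_spec("conserved", shift = 1), "conserved")
  expect_error(scenario_spec("expanded", shift = 0), "non-zero")
})

test_that("scenario stacks can carry a derived altitude layer", {
  sp <- species_spec(c(0, 0, 0), c(0.75, 0.75, 0.75))
  pair <- make_scenario_pair(
    landscape_spec("n", 50, 50, seed = 1),
    landscape_spec("i", 50, 50, origin_lon = 90, seed = 2),
    sp, scenario_spec("conserved"), 100, 100,
    seed = 5
  )
  alt <- pair$native$stack$layers$alt
  expect_true(all(alt >= 0, na.rm = TRUE))
  expect_gt(cor(as.vector(alt), as.vector(pair$native$stack$layers$env1)), 0.9)
})
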