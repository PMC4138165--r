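# shared fast fixture for the model tests
sdm_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- small_world(seed = 41, n_rows = 60, n_cols = 60, n_occ = 200, n_bg = 2000, breadth = 0.5)
      cache <<- w
    }
    cache
  }
})

test_that("an overwhelming penalty collapses all coefficients to zero", {
  w <- sdm_world()
  m <- fit_maxent(w$stack, w$bg, w$occ, beta = 1e6)
  expect_true(all(abs(m$lambda) < 1e-8))
  suit <- predict(m, extract_env(w$stack, w$bg$points$lon, w$bg$points$lat))
  expect_equal(suit, rep(0.5, length(suit)), tolerance = 1e-6)
})

test_that("the fitted linear coefficient tracks the direction of selection", {
  # presences drawn from high values of a single variable
  st <- make_landscape(landscape_spec("r", 50, 50, n_layers = 2, seed = 43))
  st1 <- climate_stack(st$layers["env1"], st$xmin, st$ymax, st$cell_size)
  bg <- sample_background(st1, stack_bounds(st1), 2000, seed = 44)
  v <- st1$layers$env1
  suit <- suitability_map(
    matrix(plogis(3 * as.vector(v)), nrow(v), ncol(v)),
    st1$xmin, st1$ymax, st1$cell_size
  )
  occ <- sample_occurrences(suit, 200, seed = 45)
  m <- fit_maxent(st1, bg, occ, beta = 1, quadratic = FALSE)
  expect_gt(m$lambda[["env1"]], 0)
})

test_that("the penalized objective is concave: common optimum from random starts", {
  w <- sdm_world()
  set.seed(46)
  objs <- vapply(1:3, function(i) {
    fit_maxent(w$stack, w$bg, w$occ, beta = 1, start = rnorm(6, 0, 2))$objective
  }, numeric(1))
  expect_lt(max(objs) - min(objs), 1e-6)
})

test_that("stronger regularization never adds active features", {
  w <- sdm_world()
  nz <- vapply(c(0.5, 1, 2, 4), function(b) {
    sum(abs(fit_maxent(w$stack, w$bg, w$occ, beta = b, products = TRUE)$lambda) > 1e-6)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("AUC: perfect ranking, ties, and invariance to monotone transforms", {
  expect_equal(auc_rank(c(0.8, 0.9, 0.95), c(0.1, 0.2, 0.3)), 1)
  expect_equal(auc_rank(c(0.2, 0.8), c(0.2, 0.8)), 0.5) # full ties split evenly
  set.seed(47)
  pos <- runif(40)
  neg <- runif(60)
  a <- auc_rank(pos, neg)
  expect_equal(auc_rank(qlogis(pos), qlogis(neg)), a)
  expect_equal(auc_rank(pos^3, neg^3), a)
})

test_that("rank AUC equals trapezoidal ROC integration on a toy set", {
  # brute-force ROC: sweep thresholds over unique scores, integrate
  roc_auc <- function(pos, neg) {
    th <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  pos <- c(0.9, 0.8, 0.7, 0.6, 0.4)
  neg <- c(0.75, 0.5, 0.3, 0.2, 0.1)
  expect_equal(auc_rank(pos, neg), roc_auc(pos, neg))
  set.seed(48)
  for (i in 1:10) {
    p <- round(runif(6), 2)
    n <- round(runif(7), 2)
    expect_equal(auc_rank(p, n), roc_auc(p, n))
  }
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(49)
  scores <- runif(500)
  lab <- sample(c(TRUE, FALSE), 500, replace = TRUE, prob = c(0.3, 0.7))
  expect_lt(abs(auc_rank(scores[lab], scores[!lab]) - 0.5), 0.08)
})

test_that("percentile threshold is the nearest-rank order statistic", {
  expect_equal(threshold_percentile(seq(0.1, 1, by = 0.1), 10), 0.1)
  expect_equal(threshold_percentile(rep(0.42, 25), 10), 0.42)
  expect_error(threshold_percentile(numeric(0)), "no presence")
  # background points play no role
  expect_equal(
    threshold_percentile(c(0.5, 0.6, 0.7, 0.8, 0.9, 0.55, 0.65, 0.75, 0.85, 0.95), 10),
    0.5
  )
})

test_that("projection onto the training stack is the identity; shifts flag extrapolation", {
  w <- sdm_world()
  m <- fit_maxent(w$stack, w$bg, w$occ, beta = 1)
  proj <- project_sdm(m, w$stack)
  # scores at background points equal direct prediction
  direct <- predict(m, extract_env(w$stack, w$bg$points$lon, w$bg$points$lat))
  via_map <- suitability_at(proj, w$bg$points)
  expect_equal(via_map, direct, tolerance = 1e-12)
  expect_false(any(proj$extrapolation &
    w$stack$layers$env1 >= m$var_range$min["env1"] &
    w$stack$layers$env1 <= m$var_range$max["env1"] &
    w$stack$layers$env2 >= m$var_range$min["env2"] &
    w$stack$layers$env2 <= m$var_range$max["env2"] &
    w$stack$layers$env3 >= m$var_range$min["env3"] &
    w$stack$layers$env3 <= m$var_range$max["env3"]))

  shifted <- w$stack
  shifted$layers$env1 <- shifted$layers$env1 + 10
  shifted <- climate_stack(shifted$layers, shifted$xmin, shifted$ymax, shifted$cell_size)
  proj_s <- project_sdm(m, shifted)
  expect_true(any(proj_s$extrapolation))

  dropped <- climate_stack(w$stack$layers[c("env1", "env2")], w$stack$xmin, w$stack$ymax, w$stack$cell_size)
  expect_error(project_sdm(m, dropped), "env3")
})

test_that("replicated evaluation returns per-replicate AUCs and averaged projections", {
  w <- sdm_world()
  ev <- evaluate_sdm(w$stack, w$bg, w$occ,
    beta = 1, n_replicates = 3, seed = 50,
    project_to = list(home = w$stack)
  )
  expect_equal(nrow(ev$replicates), 3)
  expect_true(all(ev$replicates$auc_test > 0.5))
  expect_equal(ev$auc_test, mean(ev$replicates$auc_test))
  expect_s3_class(ev$projections$home, "suitability_map")
  expect_true(all(ev$projections$home$values >= 0 & ev$projections$home$values <= 1,
    na.rm = TRUE
  ))
  expect_error(
    evaluate_sdm(w$stack, w$bg, w$occ[1:8, ], n_replicates = 2, seed = 1),
    "test split"
  )
})

test_that("tidy and glance expose coefficients and fit summaries", {
  w <- sdm_world()
  m <- fit_maxent(w$stack, w$bg, w$occ, beta = 1)
  td <- tidy(m)
  expect_setequal(td$type, c("linear", "quadratic"))
  expect_equal(nrow(td), 6)
  gl <- glance(m)
  expect_equal(gl$beta, 1)
  expect_equal(gl$n_features, 6)
})

test_that("binary range comparison: identity, nesting, and the equator cell area", {
  v <- matrix(runif(400), 20, 20)
  m1 <- suitability_map(v, 0, 10, 0.5)
  expect_equal(
    compare_binary_ranges(m1, m1, 0.5, 0.5)$frac_1_in_2, 1
  )
  expect_equal(compare_binary_ranges(m1, m1, 0.5, 0.5)$area_only1_km2, 0)

  # map1 presence strictly inside map2 presence
  v2 <- matrix(0, 20, 20)
  v2[5:15, 5:15] <- 1
  v1 <- matrix(0, 20, 20)
  v1[8:12, 8:12] <- 1
  cmp <- compare_binary_ranges(
    suitability_map(v1, 0, 10, 0.5), suitability_map(v2, 0, 10, 0.5), 0.5, 0.5
  )
  expect_equal(cmp$frac_1_in_2, 1)
  expect_lt(cmp$frac_2_in_1, 1)
  expect_equal(cmp$area_only1_km2, 0)
  # components partition the union
  expect_equal(
    cmp$area_only1_km2 + cmp$area_only2_km2 + cmp$area_both_km2,
    cmp$area_map1_km2 + cmp$area_map2_km2 - cmp$area_both_km2
  )

  # a single 1-degree presence cell centred on the equator
  one <- matrix(0, 2, 2)
  one[1, 1] <- 1 # row 1 spans lat 0..1? centre at 0 requires ymax = 0.5
  m_eq <- suitability_map(one, 0, 0.5, 1)
  a <- compare_binary_ranges(m_eq, m_eq, 0.5, 0.5)$area_map1_km2
  expect_equal(a, 111.320 * 110.574, tolerance = 1e-6)
})
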