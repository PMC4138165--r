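#' @section Model:
#' The distribution model is a Gibbs (maximum-entropy) density over the
#' background: with features `f(x)` scaled to \[0, 1\] over the background
#' sample and coefficients `lambda`, the model maximizes the penalized
#' log-likelihood
#' `sum_presences lambda.f(x) - n_pres * log sum_background exp(lambda.f(x))
#'  - beta * sum_j s_j |lambda_j|`
#' where `s_j` is the feature's standard deviation over the presences and
#' `beta` a single global regularization multiplier. The objective is
#' concave; it is maximized by L-BFGS-B on the split-variable form
#' (`lambda = a - b`, `a, b >= 0`), which handles the L1 penalty exactly.
#' Reported suitability is the logistic output with default prevalence
#' 0.5: `plogis(lambda.f(x) - log Z + H)`, `H` the entropy of the fitted
#' density over the background.
#' @name sdm-model
#' @keywords internal
NULL

# ---- feature construction ----------------------------------------------

build_feature_defs <- function(vars, quadratic = TRUE, products = FALSE) {
  defs <- lapply(vars, function(v) list(type = "linear", vars = v))
  if (quadratic) {
    defs <- c(defs, lapply(vars, function(v) list(type = "quadratic", vars = v)))
  }
  if (products && length(vars) >= 2) {
    cmb <- utils::combn(vars, 2, simplify = FALSE)
    defs <- c(defs, lapply(cmb, function(p) list(type = "product", vars = p)))
  }
  defs
}

feature_name <- function(def) {
  switch(def$type,
    linear = def$vars,
    quadratic = paste0(def$vars, "^2"),
    product = paste(def$vars, collapse = ":")
  )
}

raw_features <- function(env, defs) {
  env <- as.matrix(env)
  out <- vapply(defs, function(d) {
    switch(d$type,
      linear = env[, d$vars[1]],
      quadratic = env[, d$vars[1]]^2,
      product = env[, d$vars[1]] * env[, d$vars[2]]
    )
  }, numeric(nrow(env)))
  colnames(out) <- vapply(defs, feature_name, character(1))
  out
}

scale01 <- function(F, f_min, f_max) {
  sweep(sweep(F, 2, f_min), 2, pmax(f_max - f_min, .Machine$double.eps), "/")
}

# ---- core fit -----------------------------------------------------------

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Maximize the penalized Gibbs log-likelihood. Fp, Fb: presence and
# background feature matrices (already scaled); s: per-feature penalty
# scale; start: optional lambda start.
fit_gibbs <- function(Fp, Fb, beta, s, start = NULL,
                      maxit = 2000, pgtol = 1e-6) {
  p <- ncol(Fb)
  n_pres <- nrow(Fp)
  col_pres <- colSums(Fp)

  negobj <- function(theta) {
    lam <- theta[1:p] - theta[p + 1:p]
    lin <- drop(Fb %*% lam)
    lz <- logsumexp(lin)
    -(sum(Fp %*% lam) - n_pres * lz) + beta * sum(s * (theta[1:p] + theta[p + 1:p]))
  }
  neggrad <- function(theta) {
    lam <- theta[1:p] - theta[p + 1:p]
    lin <- drop(Fb %*% lam)
    q <- exp(lin - logsumexp(lin))
    g <- col_pres - n_pres * drop(crossprod(Fb, q))
    c(-g + beta * s, g + beta * s)
  }

  theta0 <- if (is.null(start)) {
    rep(0, 2 * p)
  } else {
    c(pmax(start, 0), pmax(-start, 0))
  }
  fit <- stats::optim(theta0, negobj, neggrad,
    method = "L-BFGS-B", lower = 0,
    control = list(maxit = maxit, factr = 10, pgtol = pgtol)
  )
  if (fit$convergence != 0) {
    stop(
      "maxent optimizer failed to converge (code ", fit$convergence,
      "): ", fit$message,
      call. = FALSE
    )
  }
  lambda <- fit$par[1:p] - fit$par[p + 1:p]
  lin_bg <- drop(Fb %*% lambda)
  lz <- logsumexp(lin_bg)
  q <- exp(lin_bg - lz)
  list(
    lambda = lambda,
    objective = -fit$value,
    log_z = lz,
    entropy = -sum(ifelse(q > 0, q * log(q), 0)),
    counts = fit$counts
  )
}

#' Fit a regularized maximum-entropy distribution model
#'
#' Presence/background SDM with linear and quadratic features (pairwise
#' products optional), each scaled to \[0, 1\] over the background, and an
#' L1 penalty `beta * s_j` per feature (`s_j` = feature SD over the
#' presences). See the package vignette for the full model statement.
#'
#' @param stack a [climate_stack()] supplying the environment.
#' @param bg a `background_region` from [sample_background()].
#' @param occ filtered presence records (>= 10).
#' @param beta global regularization multiplier (>= 0; default 1).
#' @param quadratic include per-variable quadratic features (default
#'   `TRUE`).
#' @param products include pairwise product features (default `FALSE`).
#' @param start optional coefficient start values (for convexity checks).
#' @return An `sdm_maxent` model object.
#' @export
fit_maxent <- function(stack, bg, occ, beta = 1, quadratic = TRUE,
                       products = FALSE, start = NULL) {
  stopifnot(beta >= 0)
  if (nrow(occ) < 10) stop("need at least 10 presences", call. = FALSE)
  env_pres <- extract_env(stack, occ$lon, occ$lat)
  env_bg <- extract_env(stack, bg$points$lon, bg$points$lat)
  keep <- stats::complete.cases(env_pres)
  env_pres <- env_pres[keep, ]
  env_bg <- env_bg[stats::complete.cases(env_bg), ]

  vars <- names(stack$layers)
  defs <- build_feature_defs(vars, quadratic, products)
  Fb_raw <- raw_features(env_bg, defs)
  f_min <- apply(Fb_raw, 2, min)
  f_max <- apply(Fb_raw, 2, max)
  degenerate <- f_max - f_min <= 0
  if (any(degenerate)) {
    warning(
      "dropping degenerate feature(s): ",
      paste(colnames(Fb_raw)[degenerate], collapse = ", "),
      call. = FALSE
    )
    defs <- defs[!degenerate]
    Fb_raw <- Fb_raw[, !degenerate, drop = FALSE]
    f_min <- f_min[!degenerate]
    f_max <- f_max[!degenerate]
  }
  Fb <- scale01(Fb_raw, f_min, f_max)
  Fp <- scale01(raw_features(env_pres, defs), f_min, f_max)
  s <- apply(Fp, 2, stats::sd)

  fit <- fit_gibbs(Fp, Fb, beta, s, start = start)
  structure(
    list(
      variables = vars,
      feature_defs = defs,
      feature_names = colnames(Fb),
      f_min = f_min, f_max = f_max,
      lambda = stats::setNames(fit$lambda, colnames(Fb)),
      penalty_scale = s,
      beta = beta,
      log_z = fit$log_z,
      entropy = fit$entropy,
      objective = fit$objective,
      n_presences = nrow(env_pres),
      n_background = nrow(env_bg),
      var_range = list(
        min = vapply(env_bg, min, numeric(1)),
        max = vapply(env_bg, max, numeric(1))
      )
    ),
    class = "sdm_maxent"
  )
}

#' @export
print.sdm_maxent <- function(x, ...) {
  cat(sprintf(
    "<sdm_maxent> %d features (%d non-zero), beta = %g, %d presences / %d background\n",
    length(x$lambda), sum(abs(x$lambda) > 1e-6), x$beta,
    x$n_presences, x$n_background
  ))
  invisible(x)
}

#' Predict logistic suitability for environment values
#'
#' @param object an `sdm_maxent` model.
#' @param newdata a data frame of environment values with the model's
#'   variables as columns.
#' @param ... unused.
#' @return Numeric vector of suitabilities in \[0, 1\].
#' @export
predict.sdm_maxent <- function(object, newdata, ...) {
  F <- scale01(
    raw_features(newdata[, object$variables], object$feature_defs),
    object$f_min, object$f_max
  )
  lin <- drop(F %*% object$lambda)
  stats::plogis(lin - object$log_z + object$entropy)
}

#' Project a fitted model across a region
#'
#' Features are computed with the training normalization constants (no
#' re-scaling on the target). Cells whose environment falls outside the
#' training background range on any variable are still scored but flagged
#' in the `extrapolation` element of the result.
#'
#' @param model an `sdm_maxent` model.
#' @param stack_target a [climate_stack()] carrying every model variable.
#' @return A [suitability_map()] with an `extrapolation` logical matrix.
#' @export
project_sdm <- function(model, stack_target) {
  missing <- setdiff(model$variables, names(stack_target$layers))
  if (length(missing) > 0) {
    stop("target stack lacks variable(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  env <- tibble::as_tibble(lapply(
    stack_target$layers[model$variables],
    as.vector
  ))
  ok <- stats::complete.cases(env)
  vals <- rep(NA_real_, nrow(env))
  vals[ok] <- predict(model, env[ok, ])
  d <- stack_dim(stack_target)
  extrap <- matrix(FALSE, d[1], d[2])
  for (v in model$variables) {
    x <- stack_target$layers[[v]]
    extrap <- extrap |
      (!is.na(x) & (x < model$var_range$min[v] | x > model$var_range$max[v]))
  }
  out <- suitability_map(matrix(vals, d[1], d[2]),
    xmin = stack_target$xmin, ymax = stack_target$ymax,
    cell_size = stack_target$cell_size,
    provenance = paste0("maxent beta=", model$beta)
  )
  out$extrapolation <- extrap
  out
}

#' Suitability values at point locations
#'
#' @param map a [suitability_map()].
#' @param points tibble with `lon`, `lat`.
#' @return Numeric vector (NA off-grid or on nodata).
#' @export
suitability_at <- function(map, points) {
  st <- climate_stack(list(suit = map$values), map$xmin, map$ymax, map$cell_size)
  extract_env(st, points$lon, points$lat)$suit
}

# ---- evaluation ---------------------------------------------------------

#' Rank-based AUC (Mann-Whitney formulation, ties count one half)
#'
#' @param scores_presence,scores_background score vectors.
#' @return The probability that a random presence outranks a random
#'   background point.
#' @export
auc_rank <- function(scores_presence, scores_background) {
  np <- length(scores_presence)
  nb <- length(scores_background)
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Replicated train/test evaluation (and optional averaged projection)
#'
#' Per replicate: a random `train_fraction` share of the presences is
#' used to refit the model, training AUC is computed on the training
#' presences and test AUC on the held-out presences, both against the
#' background sample. When target stacks are supplied the replicate
#' models are projected onto each and the suitability maps averaged —
#' the replicate-and-average convention for final prediction surfaces.
#'
#' @param stack,bg,occ as in [fit_maxent()].
#' @param beta,quadratic,products model settings, as in [fit_maxent()].
#' @param train_fraction share of presences used for training (default
#'   0.75).
#' @param n_replicates number of random splits (default 10).
#' @param seed integer seed.
#' @param project_to optional named list of [climate_stack()]s.
#' @return An `sdm_evaluation`: `replicates` tibble (`replicate`,
#'   `auc_train`, `auc_test`), means `auc_train` / `auc_test`, and
#'   `projections` (named list of averaged [suitability_map()]s).
#' @export
evaluate_sdm <- function(stack, bg, occ, beta = 1, train_fraction = 0.75,
                         n_replicates = 10, seed = 1, quadratic = TRUE,
                         products = FALSE, project_to = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- nrow(occ)
  n_train <- round(train_fraction * n)
  if (n - n_train < 3) stop("test split smaller than 3 presences", call. = FALSE)

  proj_sum <- NULL
  if (!is.null(project_to)) {
    proj_sum <- lapply(project_to, function(st) {
      matrix(0, stack_dim(st)[1], stack_dim(st)[2])
    })
  }
  env_bg <- extract_env(stack, bg$points$lon, bg$points$lat)
  env_bg <- env_bg[stats::complete.cases(env_bg), ]
  rows <- vector("list", n_replicates)
  set.seed(seed)
  for (r in seq_len(n_replicates)) {
    tr <- sample.int(n, n_train)
    m <- fit_maxent(stack, bg, occ[tr, ],
      beta = beta,
      quadratic = quadratic, products = products
    )
    sc_bg <- predict(m, env_bg)
    sc_tr <- predict(m, extract_env(stack, occ$lon[tr], occ$lat[tr]))
    te <- setdiff(seq_len(n), tr)
    sc_te <- predict(m, extract_env(stack, occ$lon[te], occ$lat[te]))
    rows[[r]] <- tibble::tibble(
      replicate = r,
      auc_train = auc_rank(sc_tr, sc_bg),
      auc_test = auc_rank(sc_te, sc_bg)
    )
    if (!is.null(project_to)) {
      for (nm in names(project_to)) {
        proj_sum[[nm]] <- proj_sum[[nm]] + project_sdm(m, project_to[[nm]])$values
      }
    }
  }
  reps <- dplyr::bind_rows(rows)
  projections <- NULL
  if (!is.null(project_to)) {
    projections <- lapply(names(project_to), function(nm) {
      st <- project_to[[nm]]
      suitability_map(proj_sum[[nm]] / n_replicates,
        xmin = st$xmin, ymax = st$ymax, cell_size = st$cell_size,
        provenance = paste0("mean of ", n_replicates, " replicate fits -> ", nm)
      )
    })
    names(projections) <- names(project_to)
  }
  structure(
    list(
      replicates = reps,
      auc_train = mean(reps$auc_train),
      auc_test = mean(reps$auc_test),
      n_replicates = n_replicates,
      train_fraction = train_fraction,
      beta = beta,
      projections = projections
    ),
    class = "sdm_evaluation"
  )
}

#' @export
print.sdm_evaluation <- function(x, ...) {
  cat(sprintf(
    "<sdm_evaluation> %d replicates (%.0f/%.0f split): AUC train %.3f, test %.3f\n",
    x$n_replicates, 100 * x$train_fraction, 100 * (1 - x$train_fraction),
    x$auc_train, x$auc_test
  ))
  invisible(x)
}

#' Presence-percentile suitability threshold
#'
#' The nearest-rank empirical percentile of the presence suitabilities:
#' the value at position `ceiling(percentile/100 * n)` of the sorted
#' list. Values below it are treated as unsuitable when binarizing.
#'
#' @param suit_at_presences suitability values at the presence records.
#' @param percentile percentile in (0, 100\]; default 10.
#' @return The threshold.
#' @export
threshold_percentile <- function(suit_at_presences, percentile = 10) {
  x <- suit_at_presences[!is.na(suit_at_presences)]
  if (length(x) == 0) stop("no presence suitability values", call. = FALSE)
  sort(x)[ceiling(percentile / 100 * length(x))]
}

#' @export
tidy.sdm_maxent <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_names,
    type = vapply(x$feature_defs, `[[`, character(1), "type"),
    estimate = unname(x$lambda),
    penalty_scale = unname(x$penalty_scale)
  )
}

#' @export
glance.sdm_maxent <- function(x, ...) {
  tibble::tibble(
    beta = x$beta,
    n_features = length(x$lambda),
    n_nonzero = sum(abs(x$lambda) > 1e-6),
    objective = x$objective,
    entropy = x$entropy,
    n_presences = x$n_presences,
    n_background = x$n_background
  )
}
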