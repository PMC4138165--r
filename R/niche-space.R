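#' Fit the common environmental PCA space
#'
#' Variables are standardized (zero mean, unit variance) over the pooled
#' background sample of both regions and a PCA is fitted on that pooled
#' sample; the first two components define the niche plane used for
#' gridding. The pooled score range on each retained axis is stored so
#' that native and invaded niche grids share an identical extent.
#'
#' @param stack_native,stack_invaded [climate_stack()]s with the same
#'   variable set.
#' @param bg_native,bg_invaded `background_region`s from
#'   [sample_background()].
#' @return An `env_pca` object: `means`, `scales`, `loadings`,
#'   `explained_variance_fraction`, `axis1_range`, `axis2_range`.
#' @export
fit_pca <- function(stack_native, stack_invaded, bg_native, bg_invaded) {
  vars <- names(stack_native$layers)
  if (!setequal(vars, names(stack_invaded$layers))) {
    stop("the two stacks carry different variable sets", call. = FALSE)
  }
  env <- dplyr::bind_rows(
    extract_env(stack_native, bg_native$points$lon, bg_native$points$lat),
    extract_env(stack_invaded, bg_invaded$points$lon, bg_invaded$points$lat)
  )[, vars]
  env <- env[stats::complete.cases(env), ]
  if (nrow(env) < 3) stop("need at least 3 valid background points", call. = FALSE)
  sds <- vapply(env, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("zero-variance variable(s): ", paste(vars[sds == 0], collapse = ", "),
      " (prune before ordination)",
      call. = FALSE
    )
  }
  pc <- stats::prcomp(as.matrix(env), center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1:2, drop = FALSE]
  structure(
    list(
      variables = vars,
      means = pc$center,
      scales = pc$scale,
      loadings = pc$rotation,
      explained_variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
      n_components_kept = 2L,
      axis1_range = range(scores[, 1]),
      axis2_range = range(scores[, 2])
    ),
    class = "env_pca"
  )
}

#' @export
print.env_pca <- function(x, ...) {
  ev <- 100 * x$explained_variance_fraction[1:2]
  cat(sprintf(
    "<env_pca> %d variables; axis 1: %.2f%%, axis 2: %.2f%% of variance\n",
    length(x$variables), ev[1], ev[2]
  ))
  invisible(x)
}

#' Project points into the niche plane
#'
#' Environment is extracted per point, standardized with the pooled
#' background constants, and rotated onto the first two components.
#'
#' @param pca an `env_pca` from [fit_pca()].
#' @param stack the [climate_stack()] the points live on.
#' @param points a tibble/data frame with `lon`, `lat`.
#' @return A tibble with columns `axis1`, `axis2`.
#' @export
pca_scores <- function(pca, stack, points) {
  env <- extract_env(stack, points$lon, points$lat)[, pca$variables]
  bad <- which(!stats::complete.cases(env))
  if (length(bad) > 0) {
    stop(
      "point(s) on nodata cells at indices: ",
      paste(utils::head(bad, 10), collapse = ", "),
      if (length(bad) > 10) ", ..." else "",
      call. = FALSE
    )
  }
  z <- scale(as.matrix(env), center = pca$means, scale = pca$scales)
  s <- z %*% pca$loadings[, 1:2, drop = FALSE]
  tibble::tibble(axis1 = s[, 1], axis2 = s[, 2])
}

# Silverman's rule-of-thumb bandwidth, on the scale MASS::kde2d expects
# (kde2d uses h/4 as the Gaussian sd).
silverman_h <- function(x) 4 * stats::bw.nrd0(x)

# map axis values to grid cell indices (1..R); NA when off-grid
grid_bin <- function(v, lims, R) {
  centers <- seq(lims[1], lims[2], length.out = R)
  step <- centers[2] - centers[1]
  i <- round((v - centers[1]) / step) + 1L
  i[i < 1L | i > R] <- NA_integer_
  i
}

#' Gridded niche occupancy in the PCA plane
#'
#' Projects occurrences and background points into the shared niche plane
#' and evaluates Gaussian kernel densities on an `R` x `R` grid spanning
#' the pooled background extent stored in `pca`. The occupancy density is
#' corrected for climate availability: `z = (o / e) / max(o / e)` over
#' cells inside the climatic envelope, 0 elsewhere.
#'
#' Kernel densities are strictly positive in theory, so both densities
#' are truncated to zero below the smallest density found in a grid cell
#' actually containing a point of the corresponding sample; the truncated
#' background support defines the 100% climatic envelope, and the 75%
#' envelope keeps the cells whose background density exceeds the 25th
#' percentile of the positive background densities.
#'
#' @param pca an `env_pca` from [fit_pca()].
#' @param stack the region's [climate_stack()].
#' @param bg the region's `background_region`.
#' @param occ the region's filtered occurrence tibble (>= 5 records).
#' @param R grid resolution per axis (default 100, minimum 25).
#' @param bandwidth optional numeric of length 2 overriding the
#'   per-axis Silverman bandwidths (on the [MASS::kde2d()] `h` scale).
#' @param correct divide occurrence density by background density
#'   (default `TRUE`); when `FALSE`, `z = o / max(o)` on the envelope.
#' @param region_id label carried into plots and reports.
#' @return A `niche_grid`: densities `o`, `e`, occupancy `z`, envelope
#'   masks, axis cell centers.
#' @export
build_niche_grid <- function(pca, stack, bg, occ, R = 100, bandwidth = NULL,
                             correct = TRUE, region_id = "") {
  if (R < 25) stop("R must be at least 25", call. = FALSE)
  if (nrow(occ) < 5) {
    stop("need at least 5 occurrences for stable kernel bandwidths", call. = FALSE)
  }
  so <- pca_scores(pca, stack, occ)
  sb <- pca_scores(pca, stack, bg$points)
  lims <- c(pca$axis1_range, pca$axis2_range)

  kd <- function(s) {
    h <- bandwidth %||% c(silverman_h(s$axis1), silverman_h(s$axis2))
    MASS::kde2d(s$axis1, s$axis2, h = pmax(h, 1e-6), n = R, lims = lims)
  }
  ko <- kd(so)
  ke <- kd(sb)

  truncate_density <- function(dens, s) {
    i <- grid_bin(s$axis1, lims[1:2], R)
    j <- grid_bin(s$axis2, lims[3:4], R)
    ok <- !is.na(i) & !is.na(j)
    if (!any(ok)) {
      return(dens) # no point falls on the grid; keep the full density
    }
    th <- min(dens[cbind(i[ok], j[ok])])
    dens[dens < th] <- 0
    dens
  }
  o <- truncate_density(ko$z, so)
  e <- truncate_density(ke$z, sb)

  env100 <- e > 0
  o[!env100] <- 0 # occupancy only defined where climate is available
  if (!any(env100)) stop("empty climatic envelope", call. = FALSE)
  q25 <- stats::quantile(e[env100], 0.25, names = FALSE)
  env75 <- env100 & e >= q25

  z <- matrix(0, R, R)
  if (correct) {
    r <- o[env100] / e[env100]
    if (max(r) > 0) z[env100] <- r / max(r)
  } else if (max(o) > 0) {
    z[env100] <- o[env100] / max(o)
  }

  structure(
    list(
      R = as.integer(R),
      axis1 = ko$x, axis2 = ko$y,
      axis1_range = pca$axis1_range, axis2_range = pca$axis2_range,
      o = o, e = e, z = z,
      envelope_mask_100 = env100, envelope_mask_75 = env75,
      n_occurrences = nrow(occ), region_id = region_id
    ),
    class = "niche_grid"
  )
}

#' @export
print.niche_grid <- function(x, ...) {
  cat(sprintf(
    "<niche_grid> %s: %d x %d cells, %d occurrences, envelope %d/%d cells (100%%/75%%)\n",
    x$region_id, x$R, x$R, x$n_occurrences,
    sum(x$envelope_mask_100), sum(x$envelope_mask_75)
  ))
  invisible(x)
}

#' @export
as_tibble.niche_grid <- function(x, ...) {
  g <- expand.grid(i = seq_len(x$R), j = seq_len(x$R))
  tibble::tibble(
    axis1 = x$axis1[g$i], axis2 = x$axis2[g$j],
    occurrence_density = as.vector(x$o),
    background_density = as.vector(x$e),
    occupancy = as.vector(x$z),
    in_envelope_100 = as.vector(x$envelope_mask_100),
    in_envelope_75 = as.vector(x$envelope_mask_75)
  )
}

same_grid_geometry <- function(a, b, tol = 1e-9) {
  a$R == b$R &&
    all(abs(a$axis1_range - b$axis1_range) < tol) &&
    all(abs(a$axis2_range - b$axis2_range) < tol)
}
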