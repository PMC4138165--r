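#' Virtual landscape specification
#'
#' Describes a rectangular region of spatially autocorrelated, mutually
#' correlated synthetic climate layers. Layers are built as seeded Gaussian
#' white noise mixed with a shared latent field (inducing the target
#' pairwise correlation), smoothed with a Gaussian filter of standard
#' deviation `spatial_smoothing` cells, standardized to mean 0 / SD 1, and
#' finished with a deterministic north-south gradient (SD 0.3) that mimics
#' the latitudinal structure of real bioclim variables.
#'
#' @param region_id label for the region (e.g. `"native"`).
#' @param n_rows,n_cols grid size in cells (each at least 10).
#' @param origin_lon,origin_lat north-west corner of the grid (degrees).
#' @param cell_size degrees per cell.
#' @param n_layers number of climate layers (at least 2).
#' @param spatial_smoothing Gaussian smoothing length scale, in cells
#'   (0 = white noise).
#' @param layer_correlation target pairwise correlation between layers,
#'   in \[-1, 1\]. Negative targets alternate sign between consecutive
#'   layers (all-pairs negative correlation is not attainable for more
#'   than two layers).
#' @param seed integer; the same spec and seed reproduce identical layers.
#' @return A `landscape_spec` object.
#' @export
landscape_spec <- function(region_id, n_rows, n_cols,
                           origin_lon = 0, origin_lat = 0,
                           cell_size = 0.05, n_layers = 3,
                           spatial_smoothing = 4,
                           layer_correlation = 0.3, seed = 1) {
  if (n_rows < 10 || n_cols < 10) {
    stop("invalid landscape spec: n_rows and n_cols must be >= 10", call. = FALSE)
  }
  if (n_layers < 2) stop("invalid landscape spec: n_layers must be >= 2", call. = FALSE)
  if (spatial_smoothing < 0) stop("invalid landscape spec: spatial_smoothing must be >= 0", call. = FALSE)
  if (abs(layer_correlation) > 1) {
    stop("invalid landscape spec: layer_correlation must lie in [-1, 1]", call. = FALSE)
  }
  structure(
    list(
      region_id = region_id, n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols), origin_lon = origin_lon,
      origin_lat = origin_lat, cell_size = cell_size,
      n_layers = as.integer(n_layers),
      spatial_smoothing = spatial_smoothing,
      layer_correlation = layer_correlation, seed = as.integer(seed)
    ),
    class = "landscape_spec"
  )
}

#' Virtual species specification
#'
#' The species' suitability is a product of per-axis Gaussians in
#' environment space: at environment `x`,
#' `suit(x) = max_suitability * exp(-0.5 * sum(((x - center) / breadth)^2))`,
#' so suitability equals `max_suitability` at the niche center and is
#' strictly positive everywhere.
#'
#' @param niche_center numeric vector, optimum in layer units.
#' @param niche_breadth per-axis standard deviations (layer units), same
#'   length as `niche_center`, all positive.
#' @param max_suitability peak suitability in (0, 1\].
#' @param layers optional character vector naming the stack layers the
#'   niche is defined over (default: the first `length(niche_center)`
#'   layers of the stack it is applied to).
#' @param seed integer seed carried along for downstream sampling.
#' @return A `species_spec` object.
#' @export
species_spec <- function(niche_center, niche_breadth,
                         max_suitability = 1, layers = NULL, seed = 1) {
  if (length(niche_center) != length(niche_breadth)) {
    stop("niche_center and niche_breadth must have the same length", call. = FALSE)
  }
  if (any(niche_breadth <= 0)) stop("niche_breadth must be positive", call. = FALSE)
  if (max_suitability <= 0 || max_suitability > 1) {
    stop("max_suitability must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      niche_center = as.numeric(niche_center),
      niche_breadth = as.numeric(niche_breadth),
      max_suitability = max_suitability,
      layers = layers, seed = as.integer(seed)
    ),
    class = "species_spec"
  )
}

#' Niche-dynamics scenario specification
#'
#' Encodes the ground truth of a native/invaded pair: `conserved` (same
#' niche, same kind of landscape), `unfilled` (the invaded background is
#' clipped to the central climate envelope of the native background, so
#' part of the native niche has no invaded analogue) or `expanded` (the
#' invaded population's niche center is shifted).
#'
#' @param kind one of `"conserved"`, `"unfilled"`, `"expanded"`.
#' @param shift environment-space shift of the invaded niche center
#'   (expanded scenarios; must be non-zero there, zero otherwise).
#' @param truncation_quantile width of the central native climate envelope
#'   the invaded background is clipped to (unfilled scenarios; e.g. 0.5
#'   keeps cells between the 25th and 75th native percentile of every
#'   niche layer).
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(kind = c("conserved", "unfilled", "expanded"),
                          shift = 0, truncation_quantile = 0) {
  kind <- match.arg(kind)
  if (truncation_quantile < 0 || truncation_quantile > 1) {
    stop("truncation_quantile must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "conserved" && (any(shift != 0) || truncation_quantile != 0)) {
    stop("a conserved scenario has shift = 0 and truncation_quantile = 0", call. = FALSE)
  }
  if (kind == "expanded" && all(shift == 0)) {
    stop("an expanded scenario requires a non-zero shift", call. = FALSE)
  }
  structure(
    list(kind = kind, shift = shift, truncation_quantile = truncation_quantile),
    class = "scenario_spec"
  )
}

# Separable Gaussian smoothing with edge renormalization: each output cell
# is the kernel-weighted mean of the in-window input cells.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) {
    return(m)
  }
  r <- ceiling(3 * sigma)
  w <- stats::dnorm(-r:r, sd = sigma)
  band <- function(n) {
    b <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      wi <- w[j - i + r + 1]
      b[i, j] <- wi / sum(wi)
    }
    b
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Generate a virtual climate landscape
#'
#' @param spec a [landscape_spec()].
#' @return A [climate_stack()] with layers `env1 ... envK`, each with
#'   (approximately) zero mean and unit variance plus a fixed latitudinal
#'   gradient. Pairwise layer correlations track
#'   `spec$layer_correlation` (within about 0.15 for grids of 50 x 50 or
#'   larger).
#' @export
make_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$n_rows
  nc <- spec$n_cols
  k <- spec$n_layers
  set.seed(spec$seed)
  # independent smoothed fields; smoothing shrinks the effective degrees
  # of freedom, so raw fields would show large spurious correlations.
  # Empirically orthonormalizing them and mixing through the Cholesky
  # factor of the target correlation matrix pins the pairwise
  # correlations of the noise component at the target exactly.
  F <- vapply(seq_len(k), function(i) {
    f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), spec$spatial_smoothing)
    as.vector(f)
  }, numeric(nr * nc))
  grad <- matrix(rep(seq_len(nr), nc), nr, nc)
  grad <- (grad - mean(grad)) / stats::sd(grad) * 0.3
  # leading with the gradient direction makes every noise field exactly
  # uncorrelated with it (and with the other fields)
  F <- scale(cbind(as.vector(grad), F), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(F))[, -1, drop = FALSE] * sqrt(nr * nc - 1)
  rho <- spec$layer_correlation
  sgn <- if (rho >= 0) rep(1, k) else (-1)^seq_len(k)
  C <- (1 - abs(rho)) * diag(k) + abs(rho) * tcrossprod(sgn)
  X <- Q %*% chol(C)
  layers <- lapply(seq_len(k), function(i) matrix(X[, i], nr, nc) + grad)
  names(layers) <- paste0("env", seq_len(k))
  climate_stack(layers,
    xmin = spec$origin_lon, ymax = spec$origin_lat,
    cell_size = spec$cell_size
  )
}

#' Suitability map container
#'
#' @param values numeric matrix of per-cell suitability in \[0, 1\]
#'   (`NA` = nodata).
#' @param xmin,ymax,cell_size grid geometry, as in [climate_stack()].
#' @param provenance free-form label (model / projection region).
#' @return A `suitability_map` object.
#' @export
suitability_map <- function(values, xmin, ymax, cell_size, provenance = "") {
  structure(
    list(
      values = values, xmin = xmin, ymax = ymax,
      cell_size = cell_size, provenance = provenance
    ),
    class = "suitability_map"
  )
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf(
    "<suitability_map> %d x %d cells [%s]\n  range: %.3f .. %.3f\n",
    nrow(x$values), ncol(x$values), x$provenance,
    min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)
  ))
  invisible(x)
}

#' Gaussian-niche suitability of a virtual species over a landscape
#'
#' @param stack a [climate_stack()].
#' @param sp a [species_spec()].
#' @return A [suitability_map()]; nodata cells stay nodata.
#' @export
suitability_surface <- function(stack, sp) {
  lyr <- sp$layers %||% names(stack$layers)[seq_along(sp$niche_center)]
  if (!all(lyr %in% names(stack$layers))) {
    stop("species layers missing from stack: ",
      paste(setdiff(lyr, names(stack$layers)), collapse = ", "),
      call. = FALSE
    )
  }
  if (length(lyr) != length(sp$niche_center)) {
    stop("niche_center length does not match the number of niche layers", call. = FALSE)
  }
  d2 <- 0
  for (i in seq_along(lyr)) {
    d2 <- d2 + ((stack$layers[[lyr[i]]] - sp$niche_center[i]) / sp$niche_breadth[i])^2
  }
  suitability_map(sp$max_suitability * exp(-0.5 * d2),
    xmin = stack$xmin, ymax = stack$ymax, cell_size = stack$cell_size,
    provenance = "virtual-species truth"
  )
}

#' Clip a suitability surface along an environmental layer
#'
#' Sets suitability to zero wherever `layer` falls outside
#' `[lower, upper]` — used to emulate incomplete colonization of a region
#' (occurrences restricted to part of the available climate).
#'
#' @param suit a [suitability_map()].
#' @param stack the [climate_stack()] the map was built from.
#' @param layer layer name.
#' @param lower,upper inclusive bounds on the layer value.
#' @return The clipped [suitability_map()].
#' @export
clip_suitability <- function(suit, stack, layer, lower = -Inf, upper = Inf) {
  v <- stack$layers[[layer]]
  if (is.null(v)) stop("no such layer: ", layer, call. = FALSE)
  out <- suit
  bad <- !is.na(v) & (v < lower | v > upper)
  out$values[bad] <- 0
  out
}

#' Sample occurrence records proportionally to suitability
#'
#' Draws `n` cells with probability proportional to suitability and
#' returns their centers as occurrence records. By default each cell is
#' used at most once (matching the raster-cell deduplication applied to
#' real records downstream).
#'
#' @param suit a [suitability_map()].
#' @param n number of records.
#' @param seed integer seed.
#' @param dedup if `TRUE` (default) sample cells without replacement.
#' @return A tibble with columns `lon`, `lat`, `year`, `source`.
#' @export
sample_occurrences <- function(suit, n, seed, dedup = TRUE) {
  stopifnot(n >= 1)
  v <- as.vector(suit$values)
  ok <- which(!is.na(v) & v > 0)
  if (length(ok) == 0) stop("no cells with positive suitability", call. = FALSE)
  if (dedup && n > length(ok)) {
    stop(
      "n = ", n, " exceeds the ", length(ok),
      " cells with positive suitability (maximum without duplication)",
      call. = FALSE
    )
  }
  set.seed(seed)
  pick <- ok[sample.int(length(ok), n, replace = !dedup, prob = v[ok])]
  nr <- nrow(suit$values)
  row <- (pick - 1L) %% nr + 1L
  col <- (pick - 1L) %/% nr + 1L
  tibble::tibble(
    lon = suit$xmin + (col - 0.5) * suit$cell_size,
    lat = suit$ymax - (row - 0.5) * suit$cell_size,
    year = NA_integer_,
    source = "synthetic"
  )
}

#' Build a paired native/invaded virtual study system
#'
#' Generates both regions' climate stacks and occurrence samples plus the
#' true niche parameters used in each region, for use as recovery targets.
#' When `altitude = TRUE` each stack also carries an `alt` layer (metres,
#' an affine function of `env1` clipped at sea level) that stands in for
#' topography: strongly collinear with climate, so the correlation pruning
#' step removes it from modelling, while profiles can integrate over it.
#'
#' @param spec_native,spec_invaded [landscape_spec()]s for the two regions.
#' @param sp the native-range [species_spec()].
#' @param scen a [scenario_spec()].
#' @param n_native,n_invaded occurrence counts per region.
#' @param seed integer seed for the occurrence draws.
#' @param altitude add the derived `alt` layer (default `TRUE`).
#' @return A list with elements `native` and `invaded` (each holding
#'   `stack`, `suitability`, `occurrences`, `species`) and `scenario`.
#' @export
make_scenario_pair <- function(spec_native, spec_invaded, sp, scen,
                               n_native, n_invaded, seed = 1,
                               altitude = TRUE) {
  stopifnot(inherits(scen, "scenario_spec"))
  stack_n <- make_landscape(spec_native)
  stack_i <- make_landscape(spec_invaded)
  sp_n <- sp
  sp_i <- sp
  niche_layers <- sp$layers %||% names(stack_n$layers)[seq_along(sp$niche_center)]

  if (scen$kind == "expanded") {
    shift <- rep_len(scen$shift, length(sp$niche_center))
    sp_i$niche_center <- sp$niche_center + shift
  }
  if (scen$kind == "unfilled") {
    tq <- scen$truncation_quantile
    lo <- (1 - tq) / 2
    keep <- !stack_mask(stack_i)
    for (i in seq_along(niche_layers)) {
      qn <- stats::quantile(stack_n$layers[[niche_layers[i]]],
        c(lo, 1 - lo),
        na.rm = TRUE, names = FALSE
      )
      v <- stack_i$layers[[niche_layers[i]]]
      keep <- keep & !is.na(v) & v >= qn[1] & v <= qn[2]
    }
    stack_i$layers <- lapply(stack_i$layers, function(m) {
      m[!keep] <- NA_real_
      m
    })
  }
  if (altitude) {
    for (s in c("stack_n", "stack_i")) {
      st <- get(s)
      st$layers$alt <- pmax(1200 + 600 * st$layers$env1, 0)
      assign(s, climate_stack(st$layers, st$xmin, st$ymax, st$cell_size))
    }
  }
  suit_n <- suitability_surface(stack_n, sp_n)
  suit_i <- suitability_surface(stack_i, sp_i)
  list(
    native = list(
      stack = stack_n, suitability = suit_n,
      occurrences = sample_occurrences(suit_n, n_native, seed = seed + 1L),
      species = sp_n
    ),
    invaded = list(
      stack = stack_i, suitability = suit_i,
      occurrences = sample_occurrences(suit_i, n_invaded, seed = seed + 2L),
      species = sp_i
    ),
    scenario = scen
  )
}
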