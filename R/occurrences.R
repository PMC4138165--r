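#' Read occurrence records from CSV
#'
#' Expects a header with at least `lon` and `lat` columns; `year` and
#' `source` are optional and filled with `NA` when absent.
#'
#' @param path CSV file path.
#' @return A tibble with columns `lon`, `lat`, `year`, `source`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lon", "lat") %in% names(df))) {
    stop("occurrence CSV must have 'lon' and 'lat' columns", call. = FALSE)
  }
  tibble::tibble(
    lon = as.numeric(df$lon),
    lat = as.numeric(df$lat),
    year = if ("year" %in% names(df)) as.integer(df$year) else NA_integer_,
    source = if ("source" %in% names(df)) as.character(df$source) else NA_character_
  )
}

#' Filter occurrence records against a climate stack
#'
#' Applies, in order: drop records with missing coordinates; drop records
#' older than `min_year` (when given, records with unknown year are kept);
#' drop records falling outside the stack or on nodata cells; keep only
#' the first record per raster cell. The counts removed by each rule are
#' attached as the `"filter_report"` attribute (a tibble) and the
#' operation is idempotent.
#'
#' @param occ occurrence tibble (`lon`, `lat`, optionally `year`, `source`).
#' @param stack a [climate_stack()].
#' @param min_year optional integer; records strictly older are dropped.
#' @return The filtered occurrence tibble.
#' @export
filter_occurrences <- function(occ, stack, min_year = NULL) {
  n0 <- nrow(occ)
  occ <- dplyr::filter(occ, is.finite(.data$lon), is.finite(.data$lat))
  n_coord <- n0 - nrow(occ)

  n_year <- 0L
  if (!is.null(min_year) && "year" %in% names(occ)) {
    keep <- is.na(occ$year) | occ$year >= min_year
    n_year <- sum(!keep)
    occ <- occ[keep, ]
  }

  idx <- cell_index(stack, occ$lon, occ$lat)
  mask <- stack_mask(stack)
  d <- stack_dim(stack)
  lin <- ifelse(idx$inside, (idx$col - 1L) * d[1] + idx$row, NA_integer_)
  valid <- !is.na(lin) & !mask[lin]
  n_nodata <- sum(!valid)
  occ <- occ[valid, ]
  lin <- lin[valid]

  first <- !duplicated(lin)
  n_dup <- sum(!first)
  occ <- occ[first, ]

  if (nrow(occ) == 0) {
    stop("no occurrence records survive filtering", call. = FALSE)
  }
  attr(occ, "filter_report") <- tibble::tibble(
    rule = c("missing_coordinates", "before_min_year", "off_grid_or_nodata", "duplicate_cell"),
    n_dropped = c(n_coord, n_year, n_nodata, n_dup)
  )
  occ
}

#' Sample background (pseudo-absence) points in a bounding box
#'
#' Draws `n` points uniformly over the valid (non-nodata) cells of
#' `stack` that fall inside the box, placing each point at its cell
#' center. Cells are drawn with replacement by default, the natural
#' regime when the requested count approaches the number of cells.
#'
#' @param stack a [climate_stack()].
#' @param bounds numeric vector `c(west, east, south, north)` in degrees.
#' @param n number of points.
#' @param seed integer seed.
#' @param replace sample cells with replacement (default `TRUE`).
#' @return A `background_region`: list with `bounds`, `points` (tibble of
#'   `lon`, `lat`), `n_points`, `seed`.
#' @export
sample_background <- function(stack, bounds, n, seed, replace = TRUE) {
  stopifnot(length(bounds) == 4, n >= 1)
  west <- bounds[1]
  east <- bounds[2]
  south <- bounds[3]
  north <- bounds[4]
  if (!(west < east && south < north)) {
    stop("invalid bounds: need west < east and south < north", call. = FALSE)
  }
  d <- stack_dim(stack)
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  cc <- cell_center(stack, rc$row, rc$col)
  ok <- !as.vector(stack_mask(stack)) &
    cc$lon >= west & cc$lon <= east & cc$lat >= south & cc$lat <= north
  idx <- which(ok)
  if (length(idx) == 0) {
    stop("background box contains no valid cells", call. = FALSE)
  }
  if (!replace && n > length(idx)) {
    stop("box holds only ", length(idx), " valid cells; enable replacement",
      call. = FALSE
    )
  }
  set.seed(seed)
  pick <- sample(idx, n, replace = replace)
  structure(
    list(
      bounds = c(west = west, east = east, south = south, north = north),
      points = tibble::tibble(lon = cc$lon[pick], lat = cc$lat[pick]),
      n_points = n,
      seed = as.integer(seed)
    ),
    class = "background_region"
  )
}

#' @export
print.background_region <- function(x, ...) {
  cat(sprintf(
    "<background_region> %d points in [%.3f, %.3f] x [%.3f, %.3f]\n",
    x$n_points, x$bounds["west"], x$bounds["east"],
    x$bounds["south"], x$bounds["north"]
  ))
  invisible(x)
}

#' Full-extent background box of a stack
#'
#' @param stack a [climate_stack()].
#' @return `c(west, east, south, north)`.
#' @export
stack_bounds <- function(stack) {
  c(
    west = stack$xmin, east = stack_xmax(stack),
    south = stack_ymin(stack), north = stack$ymax
  )
}

#' Drop one member of every highly correlated layer pair
#'
#' Computes Pearson correlations between all layer pairs over the
#' background sample (or every valid cell, with `use = "all"`). While any
#' pair exceeds `r_max` in absolute value, the later-ordered member of
#' the currently worst pair is removed. Zero-variance layers are dropped
#' first, with a warning.
#'
#' @param stack a [climate_stack()] with at least 2 layers.
#' @param background a `background_region` (ignored when `use = "all"`).
#' @param r_max correlation threshold (default 0.90).
#' @param use `"background"` (default) or `"all"` cells.
#' @return A list: `stack` (pruned) and `report` (tibble with one row per
#'   dropped layer: `dropped`, `kept`, `r`).
#' @export
prune_correlated <- function(stack, background = NULL, r_max = 0.90,
                             use = c("background", "all")) {
  use <- match.arg(use)
  if (n_layers(stack) < 2) stop("need at least 2 layers", call. = FALSE)
  if (use == "background") {
    if (is.null(background)) stop("background sample required", call. = FALSE)
    env <- extract_env(stack, background$points$lon, background$points$lat)
  } else {
    env <- tibble::as_tibble(lapply(stack$layers, as.vector))
    env <- env[stats::complete.cases(env), ]
  }
  pr <- prune_loop(as.matrix(env), r_max)
  pruned <- climate_stack(
    stack$layers[pr$kept], stack$xmin, stack$ymax,
    stack$cell_size
  )
  list(stack = pruned, report = pr$report)
}

# Iteratively drop the later-ordered member of the worst |r| > r_max pair.
prune_loop <- function(env, r_max) {
  report <- tibble::tibble(dropped = character(), kept = character(), r = numeric())
  sds <- apply(env, 2, stats::sd)
  for (nm in colnames(env)[sds == 0 | is.na(sds)]) {
    warning("dropping zero-variance layer '", nm, "'", call. = FALSE)
    report <- dplyr::add_row(report, dropped = nm, kept = NA_character_, r = NA_real_)
    env <- env[, colnames(env) != nm, drop = FALSE]
  }
  while (ncol(env) >= 2) {
    cm <- abs(stats::cor(env))
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (cm[worst[1], worst[2]] <= r_max) break
    # keep the earlier layer in input order, drop the later one
    pair <- sort(c(worst[1], worst[2]))
    keep_nm <- colnames(env)[pair[1]]
    drop_nm <- colnames(env)[pair[2]]
    report <- dplyr::add_row(report,
      dropped = drop_nm, kept = keep_nm,
      r = stats::cor(env[, pair[1]], env[, pair[2]])
    )
    env <- env[, colnames(env) != drop_nm, drop = FALSE]
  }
  list(kept = colnames(env), report = report)
}
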