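#' Co-registered climate raster stack
#'
#' A `climate_stack` holds one or more named single-band raster layers on a
#' shared regular lon/lat grid (WGS84 decimal degrees), with a shared nodata
#' mask: a cell that is missing in any layer is treated as missing in all of
#' them. Row 1 is the northernmost row; cell addressing is 1-based. A point
#' belongs to the half-open cell `[x, x + cell) x (y - cell, y]`.
#'
#' @param layers named list of numeric matrices, all with identical
#'   dimensions. `NA` marks nodata.
#' @param xmin western edge of the grid (degrees).
#' @param ymax northern edge of the grid (degrees).
#' @param cell_size cell size in degrees (square cells).
#'
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(layers, xmin, ymax, cell_size) {
  if (!is.list(layers) || length(layers) == 0) {
    stop("`layers` must be a non-empty named list of matrices", call. = FALSE)
  }
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("layer names must be present and unique", call. = FALSE)
  }
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all layers must share the same dimensions", call. = FALSE)
  }
  if (!is.numeric(cell_size) || cell_size <= 0) {
    stop("`cell_size` must be a positive number", call. = FALSE)
  }
  layers <- lapply(layers, function(m) {
    storage.mode(m) <- "double"
    m
  })
  # union-of-nodata mask, applied to every layer
  miss <- Reduce(`|`, lapply(layers, is.na))
  layers <- lapply(layers, function(m) {
    m[miss] <- NA_real_
    m
  })
  structure(
    list(
      layers = layers,
      xmin = xmin,
      ymax = ymax,
      cell_size = cell_size,
      crs = "EPSG:4326"
    ),
    class = "climate_stack"
  )
}

#' @export
print.climate_stack <- function(x, ...) {
  d <- stack_dim(x)
  cat(sprintf(
    "<climate_stack> %d layer(s), %d x %d cells, %.6g deg/cell\n",
    n_layers(x), d[1], d[2], x$cell_size
  ))
  cat("  extent: lon [", x$xmin, ", ", stack_xmax(x), "], lat [",
    stack_ymin(x), ", ", x$ymax, "]\n",
    sep = ""
  )
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname climate_stack
#' @param x a `climate_stack`.
#' @export
n_layers <- function(x) length(x$layers)

stack_dim <- function(x) dim(x$layers[[1]])
stack_xmax <- function(x) x$xmin + ncol(x$layers[[1]]) * x$cell_size
stack_ymin <- function(x) x$ymax - nrow(x$layers[[1]]) * x$cell_size
stack_mask <- function(x) is.na(x$layers[[1]])

same_geometry <- function(a, b, tol = 1e-9) {
  all(stack_dim(a) == stack_dim(b)) &&
    abs(a$xmin - b$xmin) < tol &&
    abs(a$ymax - b$ymax) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Locate points on a stack's grid
#'
#' @param stack a `climate_stack`.
#' @param lon,lat coordinate vectors (degrees).
#' @return A tibble with columns `row`, `col` (NA when outside the extent)
#'   and `inside`.
#' @export
cell_index <- function(stack, lon, lat) {
  cs <- stack$cell_size
  d <- stack_dim(stack)
  inside <- lon >= stack$xmin & lon < stack_xmax(stack) &
    lat > stack_ymin(stack) & lat <= stack$ymax
  col <- floor((lon - stack$xmin) / cs) + 1L
  row <- ceiling((stack$ymax - lat) / cs)
  row[row == 0L & inside] <- 1L # points exactly on the northern edge
  row[!inside | is.na(inside)] <- NA_integer_
  col[!inside | is.na(inside)] <- NA_integer_
  tibble::tibble(row = row, col = col, inside = inside & !is.na(inside))
}

#' Cell-center coordinates
#'
#' @param stack a `climate_stack`.
#' @param row,col 1-based cell indices (row 1 = northernmost).
#' @return A tibble with `lon`, `lat` of cell centers.
#' @export
cell_center <- function(stack, row, col) {
  tibble::tibble(
    lon = stack$xmin + (col - 0.5) * stack$cell_size,
    lat = stack$ymax - (row - 0.5) * stack$cell_size
  )
}

#' Extract environmental values at points
#'
#' Values are taken from the cell each point falls in; points outside the
#' extent or on nodata cells yield `NA` in every layer.
#'
#' @param stack a `climate_stack`.
#' @param lon,lat coordinate vectors (degrees).
#' @return A tibble with one column per layer.
#' @export
extract_env <- function(stack, lon, lat) {
  idx <- cell_index(stack, lon, lat)
  d <- stack_dim(stack)
  lin <- ifelse(idx$inside, (idx$col - 1L) * d[1] + idx$row, NA_integer_)
  out <- lapply(stack$layers, function(m) m[lin])
  tibble::as_tibble(out)
}

#' @export
as_tibble.climate_stack <- function(x, ...) {
  d <- stack_dim(x)
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  cc <- cell_center(x, rc$row, rc$col)
  vals <- tibble::as_tibble(lapply(x$layers, as.vector))
  dplyr::bind_cols(cc, vals)
}

# ---- ESRI ASCII grid I/O ------------------------------------------------
# Plain-text raster interchange: a 6-line header (ncols, nrows, xllcorner,
# yllcorner, cellsize, NODATA_value) followed by rows north to south.

NODATA <- -9999

#' Write a stack as ESRI ASCII grids, one file per layer
#'
#' @param stack a `climate_stack`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written (named by layer).
#' @export
write_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    path <- file.path(dir, paste0(nm, ".asc"))
    m <- stack$layers[[nm]]
    m[is.na(m)] <- NODATA
    hdr <- c(
      paste("ncols", ncol(m)),
      paste("nrows", nrow(m)),
      paste("xllcorner", format(stack$xmin, digits = 15)),
      paste("yllcorner", format(stack_ymin(stack), digits = 15)),
      paste("cellsize", format(stack$cell_size, digits = 15)),
      paste("NODATA_value", NODATA)
    )
    body <- apply(m, 1L, function(r) paste(format(r, digits = 10, trim = TRUE), collapse = " "))
    writeLines(c(hdr, body), path)
    path
  }, character(1))
  invisible(paths)
}

read_asc <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  list(
    values = m,
    xmin = hdr$xllcorner,
    ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
    cell_size = hdr$cellsize
  )
}

#' Load co-registered ASCII-grid rasters into a stack
#'
#' All files must be single-band ESRI ASCII grids on an identical grid
#' (dimensions, origin, cell size). The union of the per-layer nodata cells
#' becomes the shared mask; layer order follows the input order.
#'
#' @param paths character vector of `.asc` file paths.
#' @param names optional layer names; defaults to file base names.
#' @return A [climate_stack()].
#' @export
load_stack <- function(paths, names = NULL) {
  if (length(paths) == 0) stop("no raster paths given", call. = FALSE)
  if (is.null(names)) {
    names <- sub("\\.asc$", "", basename(paths), ignore.case = TRUE)
  }
  grids <- lapply(paths, read_asc)
  ref <- grids[[1]]
  for (i in seq_along(grids)) {
    g <- grids[[i]]
    if (!all(dim(g$values) == dim(ref$values)) ||
      abs(g$xmin - ref$xmin) > 1e-9 ||
      abs(g$ymax - ref$ymax) > 1e-9 ||
      abs(g$cell_size - ref$cell_size) > 1e-9) {
      stop("grid mismatch in layer '", names[i], "' (", paths[i], ")",
        call. = FALSE
      )
    }
  }
  layers <- stats::setNames(lapply(grids, `[[`, "values"), names)
  climate_stack(layers, ref$xmin, ref$ymax, ref$cell_size)
}
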