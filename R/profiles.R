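#' Niche occupancy profile along an environmental covariate
#'
#' Integrates predicted suitability over a covariate raster (typically
#' altitude): the suitability of every valid cell is assigned to the
#' covariate bin the cell falls in, and the binned mass is normalized to
#' sum to one. The suitability-weighted mean of the covariate is
#' computed before binning.
#'
#' @param suit a [suitability_map()].
#' @param covariate a numeric matrix with the same dimensions (e.g. an
#'   altitude layer of the same stack).
#' @param bin_width bin width in covariate units (default 100, i.e.
#'   100 m for altitude).
#' @param source label for the projection the profile summarizes.
#' @return An `occupancy_profile`: tibble `bins` (`bin_lo`, `bin_hi`,
#'   `mass`), `weighted_mean`, `bin_width`, `source`.
#' @export
occupancy_profile <- function(suit, covariate, bin_width = 100, source = "") {
  stopifnot(bin_width > 0)
  if (!all(dim(suit$values) == dim(covariate))) {
    stop("suitability and covariate grids differ in shape", call. = FALSE)
  }
  ok <- !is.na(suit$values) & !is.na(covariate)
  w <- suit$values[ok]
  x <- covariate[ok]
  if (sum(w) == 0) stop("all suitability is zero; profile undefined", call. = FALSE)

  weighted_mean <- sum(w * x) / sum(w)
  lo <- floor(min(x, 0) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  mass <- vapply(
    seq_len(length(edges) - 1L),
    function(b) sum(w[bin == b]), numeric(1)
  )
  structure(
    list(
      bins = tibble::tibble(
        bin_lo = edges[-length(edges)],
        bin_hi = edges[-1],
        mass = mass / sum(mass)
      ),
      weighted_mean = weighted_mean,
      bin_width = bin_width,
      source = source
    ),
    class = "occupancy_profile"
  )
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf(
    "<occupancy_profile> %s: %d bins of %g units, weighted mean %.1f\n",
    x$source, nrow(x$bins), x$bin_width, x$weighted_mean
  ))
  invisible(x)
}

#' @export
tidy.occupancy_profile <- function(x, ...) {
  dplyr::mutate(x$bins, source = x$source)
}

#' @export
glance.occupancy_profile <- function(x, ...) {
  tibble::tibble(
    weighted_mean = x$weighted_mean,
    n_bins = nrow(x$bins),
    bin_width = x$bin_width,
    source = x$source
  )
}

# align two profiles onto the union of their bin ranges (same bin width
# required); returns a list of two mass vectors
align_profiles <- function(p1, p2) {
  if (abs(p1$bin_width - p2$bin_width) > 1e-9) {
    stop("profiles have different bin widths", call. = FALSE)
  }
  bw <- p1$bin_width
  if (abs((p1$bins$bin_lo[1] - p2$bins$bin_lo[1]) %% bw) > 1e-6 * bw &&
    abs((p1$bins$bin_lo[1] - p2$bins$bin_lo[1]) %% bw - bw) > 1e-6 * bw) {
    stop("profile bin edges are not aligned", call. = FALSE)
  }
  lo <- min(p1$bins$bin_lo[1], p2$bins$bin_lo[1])
  hi <- max(max(p1$bins$bin_hi), max(p2$bins$bin_hi))
  n <- round((hi - lo) / bw)
  place <- function(p) {
    m <- numeric(n)
    i0 <- round((p$bins$bin_lo[1] - lo) / bw)
    m[i0 + seq_len(nrow(p$bins))] <- p$bins$mass
    m
  }
  list(m1 = place(p1), m2 = place(p2))
}

#' Kolmogorov-Smirnov comparison of two occupancy profiles
#'
#' The statistic is the maximum absolute difference between the two
#' cumulative normalized mass curves. Because a suitability profile has
#' no natural sample size, the p-value is advisory: it applies the
#' asymptotic two-sample KS formula with an effective sample size equal
#' to the number of bins holding positive mass in either profile, and is
#' flagged as such.
#'
#' @param p1,p2 `occupancy_profile`s on aligned bins.
#' @return A one-row tibble: `ks_stat`, `p_value`, `n_effective`,
#'   `p_value_advisory` (always `TRUE`).
#' @export
compare_profiles <- function(p1, p2) {
  m <- align_profiles(p1, p2)
  ks <- max(abs(cumsum(m$m1) - cumsum(m$m2)))
  n_eff <- sum(m$m1 > 0 | m$m2 > 0)
  # asymptotic two-sample KS tail: n1 = n2 = n_eff
  lam <- sqrt(n_eff / 2) * ks
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))
  tibble::tibble(
    ks_stat = ks,
    p_value = min(max(p, 0), 1),
    n_effective = n_eff,
    p_value_advisory = TRUE
  )
}
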