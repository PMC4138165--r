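#' Area of one grid cell at a given latitude
#'
#' Spherical-degree approximation:
#' `km2 = (111.320 * cos(lat) * dlon) * (110.574 * dlat)`.
#'
#' @param lat latitude of the cell center (degrees).
#' @param cell_size cell edge (degrees).
#' @return Cell area in km^2.
#' @export
cell_area_km2 <- function(lat, cell_size) {
  (111.320 * cos(lat * pi / 180) * cell_size) * (110.574 * cell_size)
}

binary_area_km2 <- function(bin, ymax, cell_size) {
  lat <- ymax - (seq_len(nrow(bin)) - 0.5) * cell_size
  row_area <- cell_area_km2(lat, cell_size)
  sum(rowSums(bin, na.rm = TRUE) * row_area)
}

#' Compare two thresholded suitability maps
#'
#' Each map is binarized at its own threshold (`suitability >= threshold`
#' = presence); per-cell areas use the latitude-dependent spherical
#' formula of [cell_area_km2()]. Inclusion fractions are area-based:
#' `frac_1_in_2` is the share of map 1's predicted range that also lies
#' in map 2's.
#'
#' @param map1,map2 [suitability_map()]s on the same grid.
#' @param thr1,thr2 thresholds for the two maps.
#' @return A one-row tibble: `area_map1_km2`, `area_map2_km2`,
#'   `frac_1_in_2`, `frac_2_in_1`, `area_only1_km2`, `area_only2_km2`,
#'   `area_both_km2`.
#' @export
compare_binary_ranges <- function(map1, map2, thr1, thr2) {
  if (!all(dim(map1$values) == dim(map2$values)) ||
    abs(map1$xmin - map2$xmin) > 1e-9 ||
    abs(map1$ymax - map2$ymax) > 1e-9 ||
    abs(map1$cell_size - map2$cell_size) > 1e-9) {
    stop("suitability maps have different geometry", call. = FALSE)
  }
  b1 <- !is.na(map1$values) & map1$values >= thr1
  b2 <- !is.na(map2$values) & map2$values >= thr2
  area <- function(b) binary_area_km2(b, map1$ymax, map1$cell_size)
  a1 <- area(b1)
  a2 <- area(b2)
  both <- area(b1 & b2)
  tibble::tibble(
    area_map1_km2 = a1,
    area_map2_km2 = a2,
    frac_1_in_2 = if (a1 > 0) both / a1 else NA_real_,
    frac_2_in_1 = if (a2 > 0) both / a2 else NA_real_,
    area_only1_km2 = a1 - both,
    area_only2_km2 = a2 - both,
    area_both_km2 = both
  )
}
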