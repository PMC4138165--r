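#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|p1 - p2|)` over grid cells, where each `p` is the
#' occupancy density normalized to sum to one. Ranges from 0 (disjoint
#' niches) to 1 (identical niches); symmetric in its arguments and
#' invariant to rescaling either occupancy by a positive constant.
#'
#' @param grid1,grid2 `niche_grid`s with identical geometry.
#' @return The overlap, a number in \[0, 1\].
#' @export
schoener_d <- function(grid1, grid2) {
  if (!same_grid_geometry(grid1, grid2)) {
    stop("niche grids have different geometry", call. = FALSE)
  }
  s1 <- sum(grid1$z)
  s2 <- sum(grid2$z)
  if (s1 == 0 || s2 == 0) {
    stop("a grid with zero total occupancy has no defined overlap", call. = FALSE)
  }
  1 - 0.5 * sum(abs(grid1$z / s1 - grid2$z / s2))
}

# All rigid integer translations of `support` that keep it fully inside
# `envelope` (both R x R logical matrices). Returns a 2-column matrix of
# (di, dj) shifts.
valid_translations <- function(support, envelope) {
  R <- nrow(support)
  idx <- which(support, arr.ind = TRUE)
  r_rng <- range(idx[, 1])
  c_rng <- range(idx[, 2])
  lin0 <- (idx[, 2] - 1L) * R + idx[, 1]
  Mv <- as.vector(envelope)
  out <- list()
  k <- 0L
  for (dj in (1L - c_rng[1]):(R - c_rng[2])) {
    off_j <- dj * R
    for (di in (1L - r_rng[1]):(R - r_rng[2])) {
      if (all(Mv[lin0 + di + off_j])) {
        k <- k + 1L
        out[[k]] <- c(di, dj)
      }
    }
  }
  if (k == 0L) {
    return(matrix(integer(0), ncol = 2))
  }
  do.call(rbind, out)
}

translate_matrix <- function(m, di, dj) {
  R <- nrow(m)
  out <- matrix(0, R, R)
  src_r <- max(1, 1 - di):min(R, R - di)
  src_c <- max(1, 1 - dj):min(R, R - dj)
  out[src_r + di, src_c + dj] <- m[src_r, src_c]
  out
}

#' Niche similarity test by random translation
#'
#' Tests whether the observed overlap between two niches exceeds the
#' overlap expected if one of them occupied a random position within its
#' region's available climate. In each replicate the chosen grid's
#' occupancy density is rigidly translated to a uniformly random position
#' whose support lies fully inside that region's 100% climatic envelope
#' (no wrapping, and never the identity position — the observed
#' arrangement enters once through the plus-one estimator), and D is
#' recomputed against the other, untouched grid.
#' The p-value uses the plus-one estimator
#' `p = (1 + #(D_null >= D_obs)) / (1 + n_reps)`, so it is always in
#' (0, 1\].
#'
#' @param grid1,grid2 `niche_grid`s with identical geometry.
#' @param randomize which grid's density is relocated (1 or 2).
#' @param n_reps number of null replicates (>= 99).
#' @param seed integer seed.
#' @return A list: `p_value`, `d_observed`, `d_null` (vector),
#'   `n_valid_positions`.
#' @export
similarity_test <- function(grid1, grid2, randomize = 2, n_reps = 99, seed = 1) {
  if (n_reps < 99) stop("n_reps must be at least 99", call. = FALSE)
  if (!same_grid_geometry(grid1, grid2)) {
    stop("niche grids have different geometry", call. = FALSE)
  }
  d_obs <- schoener_d(grid1, grid2)
  g <- if (randomize == 1) grid1 else grid2
  other <- if (randomize == 1) grid2 else grid1
  support <- g$z > 0
  shifts <- valid_translations(support, g$envelope_mask_100)
  # the identity translation is the observed arrangement, which the
  # plus-one estimator already accounts for once; a relocation must move
  shifts <- shifts[!(shifts[, 1] == 0 & shifts[, 2] == 0), , drop = FALSE]
  if (nrow(shifts) == 0) {
    stop(
      "no translation keeps the occupancy support inside the envelope; ",
      "the density support is too large relative to the background",
      call. = FALSE
    )
  }
  set.seed(seed)
  pick <- sample.int(nrow(shifts), n_reps, replace = TRUE)
  gs <- g
  d_null <- vapply(pick, function(s) {
    gs$z <- translate_matrix(g$z, shifts[s, 1], shifts[s, 2])
    schoener_d(gs, other)
  }, numeric(1))
  list(
    p_value = (1 + sum(d_null >= d_obs)) / (1 + n_reps),
    d_observed = d_obs,
    d_null = d_null,
    n_valid_positions = nrow(shifts)
  )
}

#' Stability / unfilling / expansion decomposition
#'
#' Restricts the comparison to analogue climates — cells inside the
#' chosen climatic envelope of either region — and decomposes the two
#' occupancies over niche supports (`z > 0`, optionally after dropping
#' the lowest `support_quantile` fraction of density mass):
#' expansion `E` is the share of invaded density outside the native
#' support, stability `S = 1 - E` the share inside, and unfilling `U`
#' the share of native density outside the invaded support.
#'
#' @param grid_native,grid_invaded `niche_grid`s with identical geometry.
#' @param envelope `"75"` (default, analogue climates only) or `"100"`.
#' @param support_quantile fraction of the lowest density mass ignored
#'   when delimiting each niche's support (default 0).
#' @return A named numeric vector `c(S, U, E)`.
#' @export
sue_indices <- function(grid_native, grid_invaded, envelope = c("75", "100"),
                        support_quantile = 0) {
  envelope <- match.arg(as.character(envelope), c("75", "100"))
  if (!same_grid_geometry(grid_native, grid_invaded)) {
    stop("niche grids have different geometry", call. = FALSE)
  }
  mask_of <- function(g) {
    if (envelope == "75") g$envelope_mask_75 else g$envelope_mask_100
  }
  analogue <- mask_of(grid_native) | mask_of(grid_invaded)
  zn <- grid_native$z * analogue
  zi <- grid_invaded$z * analogue
  if (sum(zn) == 0 || sum(zi) == 0) {
    stop("empty niche support after envelope masking", call. = FALSE)
  }
  support <- function(z) {
    s <- z > 0
    if (support_quantile > 0) {
      v <- sort(z[s])
      cut <- v[findInterval(support_quantile * sum(v), cumsum(v)) + 1L]
      s <- z > cut
    }
    s
  }
  supp_n <- support(zn)
  supp_i <- support(zi)
  E <- sum(zi[!supp_n]) / sum(zi)
  U <- sum(zn[!supp_i]) / sum(zn)
  c(S = 1 - E, U = U, E = E)
}

#' Full niche-dynamics comparison of a native/invaded pair
#'
#' Bundles Schoener's D, the two directed similarity tests and the
#' stability/unfilling/expansion indices (on the chosen envelope, with
#' the 100% and 75% variants both reported) into one result object with
#' [generics::tidy()] / [generics::glance()] methods.
#'
#' @param grid_native,grid_invaded `niche_grid`s on the same geometry.
#' @param n_reps similarity-test replicates (default 99).
#' @param seed integer seed.
#' @param envelope envelope used for the headline S/U/E (default `"75"`).
#' @param support_quantile passed to [sue_indices()].
#' @return A `niche_dynamics` object.
#' @export
niche_dynamics <- function(grid_native, grid_invaded, n_reps = 99, seed = 1,
                           envelope = "75", support_quantile = 0) {
  # a direction can be untestable when the occupancy support fills its
  # whole envelope (no room to relocate); report NA for that direction
  try_test <- function(randomize, seed) {
    tryCatch(
      similarity_test(grid_native, grid_invaded,
        randomize = randomize,
        n_reps = n_reps, seed = seed
      ),
      error = function(e) {
        warning(conditionMessage(e), call. = FALSE)
        list(p_value = NA_real_, d_observed = schoener_d(grid_native, grid_invaded))
      }
    )
  }
  st_ni <- try_test(2, seed)
  st_in <- try_test(1, seed + 1L)
  sue <- sue_indices(grid_native, grid_invaded,
    envelope = envelope,
    support_quantile = support_quantile
  )
  sue100 <- sue_indices(grid_native, grid_invaded,
    envelope = "100",
    support_quantile = support_quantile
  )
  sue75 <- sue_indices(grid_native, grid_invaded,
    envelope = "75",
    support_quantile = support_quantile
  )
  structure(
    list(
      D = st_ni$d_observed,
      p_native_to_invaded = st_ni$p_value,
      p_invaded_to_native = st_in$p_value,
      S = unname(sue["S"]), U = unname(sue["U"]), E = unname(sue["E"]),
      sue_100 = sue100, sue_75 = sue75,
      envelope = envelope, n_reps = n_reps, seed = seed
    ),
    class = "niche_dynamics"
  )
}

#' @export
print.niche_dynamics <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Niche dynamics (envelope %s%%, %d-rep similarity tests)\n",
      "  D = %.3f (native->invaded P = %.3f; invaded->native P = %.3f)\n",
      "  stability S = %.3f, unfilling U = %.3f, expansion E = %.3f\n"
    ),
    x$envelope, x$n_reps, x$D,
    x$p_native_to_invaded, x$p_invaded_to_native, x$S, x$U, x$E
  ))
  invisible(x)
}

#' @export
tidy.niche_dynamics <- function(x, ...) {
  tibble::tibble(
    metric = c(
      "D", "p_native_to_invaded", "p_invaded_to_native",
      "S", "U", "E"
    ),
    value = c(
      x$D, x$p_native_to_invaded, x$p_invaded_to_native,
      x$S, x$U, x$E
    )
  )
}

#' @export
glance.niche_dynamics <- function(x, ...) {
  tibble::tibble(
    D = x$D,
    p_native_to_invaded = x$p_native_to_invaded,
    p_invaded_to_native = x$p_invaded_to_native,
    S = x$S, U = x$U, E = x$E,
    envelope = x$envelope, n_reps = x$n_reps
  )
}
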