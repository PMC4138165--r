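#' Analysis configuration
#'
#' Collects every tunable of the end-to-end analysis with the
#' conventional defaults: variable screening at |r| > 0.90, a 100 x 100
#' niche grid, the 75% analogue-climate envelope, maxent regularization
#' beta = 1, a 75/25 train/test split with 100 replicates, the 10th
#' presence percentile threshold, 10,000 background points, 99
#' similarity-test replicates and 100 m profile bins. Configurations
#' round-trip through YAML via [write_config()] / [read_config()].
#'
#' @param scenario list describing the synthetic scenario: `kind`
#'   (`"conserved"`, `"unfilled"`, `"expanded"`), `shift`,
#'   `truncation_quantile`. Ignored when `paths` is supplied.
#' @param landscape list of landscape settings shared by both synthetic
#'   regions: `n_rows`, `n_cols`, `n_layers`, `spatial_smoothing`,
#'   `layer_correlation`, `cell_size`.
#' @param species list: `niche_center`, `niche_breadth`,
#'   `max_suitability`.
#' @param n_occurrences occurrences sampled per synthetic region.
#' @param paths optional list for user-supplied data, with entries
#'   `native` and `invaded`, each a list `rasters` (character vector of
#'   `.asc` files) and `occurrences` (CSV path); plus optional
#'   `bounds_native`, `bounds_invaded` (west, east, south, north).
#' @param r_max correlation-pruning threshold.
#' @param R niche-grid resolution per axis.
#' @param envelope `"75"` or `"100"`, for the headline S/U/E.
#' @param beta maxent regularization multiplier.
#' @param train_fraction presence share used for training.
#' @param percentile presence percentile for the binary threshold.
#' @param n_background background points per region.
#' @param n_reps_similarity similarity-test replicates.
#' @param sdm_replicates train/test replicates averaged into the final
#'   suitability surfaces.
#' @param bin_width occupancy-profile bin width (covariate units).
#' @param covariate profile covariate layer name (default `"alt"`).
#' @param min_year optional occurrence year cutoff.
#' @param seed root seed; every stage derives its own stream from it.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(scenario = list(kind = "conserved"),
                            landscape = list(
                              n_rows = 120, n_cols = 120, n_layers = 3,
                              spatial_smoothing = 4, layer_correlation = 0.3,
                              cell_size = 0.05
                            ),
                            species = list(
                              niche_center = c(0, 0, 0),
                              niche_breadth = c(0.75, 0.75, 0.75),
                              max_suitability = 1
                            ),
                            n_occurrences = 1000,
                            paths = NULL,
                            r_max = 0.90,
                            R = 100,
                            envelope = "75",
                            beta = 1,
                            train_fraction = 0.75,
                            percentile = 10,
                            n_background = 10000,
                            n_reps_similarity = 99,
                            sdm_replicates = 100,
                            bin_width = 100,
                            covariate = "alt",
                            min_year = NULL,
                            seed = 1) {
  cfg <- list(
    scenario = scenario, landscape = landscape, species = species,
    n_occurrences = n_occurrences, paths = paths, r_max = r_max, R = R,
    envelope = as.character(envelope), beta = beta,
    train_fraction = train_fraction, percentile = percentile,
    n_background = n_background, n_reps_similarity = n_reps_similarity,
    sdm_replicates = sdm_replicates, bin_width = bin_width,
    covariate = covariate, min_year = min_year, seed = as.integer(seed)
  )
  structure(cfg, class = "analysis_config")
}

#' @rdname analysis_config
#' @param config an `analysis_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw)
}

# assemble the two regions (synthetic or from files)
resolve_inputs <- function(config) {
  if (!is.null(config$paths)) {
    load_region <- function(p) {
      list(
        stack = load_stack(p$rasters),
        occurrences = read_occurrences(p$occurrences)
      )
    }
    return(list(
      native = load_region(config$paths$native),
      invaded = load_region(config$paths$invaded),
      bounds_native = config$paths$bounds_native,
      bounds_invaded = config$paths$bounds_invaded
    ))
  }
  ls <- config$landscape
  mk_spec <- function(id, seed, east_offset = 0) {
    landscape_spec(
      region_id = id, n_rows = ls$n_rows, n_cols = ls$n_cols,
      origin_lon = east_offset, origin_lat = 0,
      cell_size = ls$cell_size, n_layers = ls$n_layers,
      spatial_smoothing = ls$spatial_smoothing,
      layer_correlation = ls$layer_correlation, seed = seed
    )
  }
  sp <- species_spec(
    config$species$niche_center, config$species$niche_breadth,
    config$species$max_suitability
  )
  scen <- scenario_spec(
    kind = config$scenario$kind,
    shift = config$scenario$shift %||% 0,
    truncation_quantile = config$scenario$truncation_quantile %||% 0
  )
  pair <- make_scenario_pair(
    mk_spec("native", config$seed + 11L),
    mk_spec("invaded", config$seed + 12L, east_offset = 90),
    sp, scen,
    n_native = config$n_occurrences, n_invaded = config$n_occurrences,
    seed = config$seed + 20L
  )
  list(
    native = pair$native, invaded = pair$invaded,
    bounds_native = NULL, bounds_invaded = NULL
  )
}

#' Run the full niche-dynamics analysis
#'
#' Executes the complete workflow: occurrence filtering, background
#' sampling, correlation pruning (over the pooled backgrounds), the
#' common environmental PCA, kernel-smoothed niche grids, overlap /
#' similarity tests / stability-unfilling-expansion, reciprocal
#' replicated maxent models projected onto the invaded region,
#' presence-percentile thresholds, binary range comparison, and
#' altitudinal occupancy profiles.
#'
#' @param config an [analysis_config()].
#' @return An `analysis_report` with blocks `niche`, `sdm`, `profile`
#'   and `provenance`; see [write_report()].
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  seed <- config$seed
  inputs <- resolve_inputs(config)
  stack_n <- inputs$native$stack
  stack_i <- inputs$invaded$stack

  occ_n <- filter_occurrences(inputs$native$occurrences, stack_n, config$min_year)
  occ_i <- filter_occurrences(inputs$invaded$occurrences, stack_i, config$min_year)

  bg_n <- sample_background(
    stack_n, inputs$bounds_native %||% stack_bounds(stack_n),
    n = config$n_background, seed = seed + 31L
  )
  bg_i <- sample_background(
    stack_i, inputs$bounds_invaded %||% stack_bounds(stack_i),
    n = config$n_background, seed = seed + 32L
  )

  # variable screening on the pooled background environments
  env_pool <- rbind(
    as.matrix(extract_env(stack_n, bg_n$points$lon, bg_n$points$lat)),
    as.matrix(extract_env(stack_i, bg_i$points$lon, bg_i$points$lat))
  )
  env_pool <- env_pool[stats::complete.cases(env_pool), , drop = FALSE]
  pr <- prune_loop(env_pool, config$r_max)
  keep_stack <- function(st) {
    climate_stack(st$layers[pr$kept], st$xmin, st$ymax, st$cell_size)
  }
  mod_stack_n <- keep_stack(stack_n)
  mod_stack_i <- keep_stack(stack_i)

  pca <- fit_pca(mod_stack_n, mod_stack_i, bg_n, bg_i)
  grid_n <- build_niche_grid(pca, mod_stack_n, bg_n, occ_n,
    R = config$R,
    region_id = "native"
  )
  grid_i <- build_niche_grid(pca, mod_stack_i, bg_i, occ_i,
    R = config$R,
    region_id = "invaded"
  )
  dyn <- niche_dynamics(grid_n, grid_i,
    n_reps = config$n_reps_similarity,
    seed = seed + 40L, envelope = config$envelope
  )

  # reciprocal SDMs, both projected onto the invaded region
  ev_n <- evaluate_sdm(mod_stack_n, bg_n, occ_n,
    beta = config$beta,
    train_fraction = config$train_fraction,
    n_replicates = config$sdm_replicates, seed = seed + 51L,
    project_to = list(invaded = mod_stack_i)
  )
  ev_i <- evaluate_sdm(mod_stack_i, bg_i, occ_i,
    beta = config$beta,
    train_fraction = config$train_fraction,
    n_replicates = config$sdm_replicates, seed = seed + 52L,
    project_to = list(invaded = mod_stack_i)
  )
  map_from_native <- ev_n$projections$invaded
  map_from_invaded <- ev_i$projections$invaded

  # thresholds from predictions at the invaded-range occurrences
  thr_n <- threshold_percentile(
    suitability_at(map_from_native, occ_i), config$percentile
  )
  thr_i <- threshold_percentile(
    suitability_at(map_from_invaded, occ_i), config$percentile
  )
  ranges <- compare_binary_ranges(map_from_invaded, map_from_native, thr_i, thr_n)

  cov <- stack_i$layers[[config$covariate]]
  profile_block <- NULL
  if (!is.null(cov)) {
    prof_n <- occupancy_profile(map_from_native, cov,
      bin_width = config$bin_width, source = "native model"
    )
    prof_i <- occupancy_profile(map_from_invaded, cov,
      bin_width = config$bin_width, source = "invaded model"
    )
    ks <- compare_profiles(prof_n, prof_i)
    profile_block <- list(
      weighted_mean_native = prof_n$weighted_mean,
      weighted_mean_invaded = prof_i$weighted_mean,
      ks_stat = ks$ks_stat, ks_p_value = ks$p_value,
      ks_p_advisory = TRUE,
      profiles = list(native = prof_n, invaded = prof_i)
    )
  }

  structure(
    list(
      niche = list(
        D = dyn$D,
        p_native_to_invaded = dyn$p_native_to_invaded,
        p_invaded_to_native = dyn$p_invaded_to_native,
        S = dyn$S, U = dyn$U, E = dyn$E,
        sue_100 = as.list(dyn$sue_100), sue_75 = as.list(dyn$sue_75),
        explained_variance = pca$explained_variance_fraction[1:2]
      ),
      sdm = list(
        auc_train_native = ev_n$auc_train, auc_test_native = ev_n$auc_test,
        auc_train_invaded = ev_i$auc_train, auc_test_invaded = ev_i$auc_test,
        threshold_native = thr_n, threshold_invaded = thr_i,
        area_from_invaded_km2 = ranges$area_map1_km2,
        area_from_native_km2 = ranges$area_map2_km2,
        frac_invaded_in_native = ranges$frac_1_in_2,
        frac_native_in_invaded = ranges$frac_2_in_1,
        ranges = ranges
      ),
      profile = profile_block,
      objects = list(
        pca = pca, grids = list(native = grid_n, invaded = grid_i),
        dynamics = dyn,
        projections = list(
          from_native = map_from_native,
          from_invaded = map_from_invaded
        ),
        prune_report = pr$report
      ),
      provenance = list(
        seed = seed,
        config_hash = rlang::hash(unclass(config)),
        package_version = as.character(utils::packageVersion("nichedyn")),
        dropped_layers = pr$report$dropped
      )
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Niche dynamics ==\n")
  cat(sprintf(
    "  D = %.3f (P %.3f / %.3f), S = %.3f, U = %.3f, E = %.3f\n",
    x$niche$D, x$niche$p_native_to_invaded, x$niche$p_invaded_to_native,
    x$niche$S, x$niche$U, x$niche$E
  ))
  cat("== SDM ==\n")
  cat(sprintf(
    "  AUC test: native %.3f, invaded %.3f; thresholds %.3f / %.3f\n",
    x$sdm$auc_test_native, x$sdm$auc_test_invaded,
    x$sdm$threshold_native, x$sdm$threshold_invaded
  ))
  cat(sprintf(
    "  areas (km2): from invaded %.0f, from native %.0f; inclusion %.1f%% / %.1f%%\n",
    x$sdm$area_from_invaded_km2, x$sdm$area_from_native_km2,
    100 * x$sdm$frac_invaded_in_native, 100 * x$sdm$frac_native_in_invaded
  ))
  if (!is.null(x$profile)) {
    cat("== Profiles ==\n")
    cat(sprintf(
      "  weighted means: native model %.0f, invaded model %.0f; KS D = %.3f\n",
      x$profile$weighted_mean_native, x$profile$weighted_mean_invaded,
      x$profile$ks_stat
    ))
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Writes the numeric blocks of the report (not the heavyweight grid
#' objects) as a machine-readable JSON record.
#'
#' @param report an `analysis_report`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  out <- list(
    niche = report$niche,
    sdm = lapply(report$sdm, function(v) if (inherits(v, "tbl_df")) as.list(v) else v),
    profile = if (!is.null(report$profile)) {
      report$profile[setdiff(names(report$profile), "profiles")]
    },
    provenance = report$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
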