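# Configuration-driven orchestration: synthetic or file inputs run through
# gap-fill -> QC -> aggregation -> trait axes -> climate/soil partition ->
# RDA, emitting a structured run report. One master seed deterministically
# spawns every stage seed.

.default_run_config <- function() {
  list(
    mode = "synthetic",
    input_dir = NA_character_,
    world = list(),                    # overrides for world_config()
    gapfill = list(enabled = TRUE, rank = 10L, noise_precision = 4,
                   max_iter = 1000L, burn_in = 200L, thin = 20L,
                   patience = 5L, stable_tol = 1e-4),
    qc = list(exclude_z = 4, flag_z = 3, filter_observed_only = FALSE),
    aggregate = list(min_species = 20L, min_fraction = 0.01),
    axes = list(cut = 1.0, n_perm = 199L, alpha = 0.05, n_axes = 5L,
                run_permutation_test = FALSE),
    partition = list(outer_folds = 10L, inner_folds = 10L, repetitions = 50L,
                     block_size = 20L, n_lambda = 100L),
    rda = list(vif_exclude = 20, vif_target = 10, topsoil_only = TRUE),
    seed = 1L,
    outdir = NA_character_,
    verbosity = 1L
  )
}

.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop(sprintf("config key '%s' must be a section", path), call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (path == "world") {
    # world section passes through to world_config(), which validates names
    return(modifyList(defaults, user))
  }
  if (length(unknown)) {
    stop(sprintf("unknown config key '%s%s'", if (nzchar(path)) paste0(path, ".") else "", unknown[1]),
         call. = FALSE)
  }
  out <- defaults
  for (nm in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (is.null(user[[nm]])) {
      # JSON null (e.g. a serialized NA path): keep the default
      next
    } else if (is.list(defaults[[nm]])) {
      out[[nm]] <- .merge_config(defaults[[nm]], user[[nm]], key)
    } else {
      out[[nm]] <- user[[nm]]
    }
  }
  out
}

#' Validate a pipeline configuration
#'
#' Fills documented defaults (>20 species and >1% richness inclusion, 10/10
#' cross-validation folds, 50 repetitions, 20 components per block, VIF
#' thresholds 20/10, z-score QC at 4 with flagging at 3, Gibbs schedule
#' 1000/200/20), rejects unknown keys, and checks constraints. Accepts a
#' config as a nested list, a JSON string, or a path to a JSON file.
#'
#' @param config nested list, JSON text, or JSON file path; `NULL` for all
#'   defaults.
#' @return validated `run_config` list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (inherits(config, "run_config")) config <- unclass(config)
  cfg <- .merge_config(.default_run_config(), config)
  check_that(cfg$mode %in% c("synthetic", "files"), "mode",
             "must be 'synthetic' or 'files'")
  if (cfg$mode == "files") {
    check_that(is.character(cfg$input_dir) && !is.na(cfg$input_dir), "input_dir",
               "required in files mode")
  }
  check_that(is_count(cfg$partition$repetitions), "partition.repetitions", "must be >= 1")
  check_that(is_count(cfg$partition$outer_folds, 2L), "partition.outer_folds", "must be >= 2")
  check_that(is_count(cfg$partition$inner_folds, 2L), "partition.inner_folds", "must be >= 2")
  check_that(is_count(cfg$partition$block_size), "partition.block_size", "must be >= 1")
  check_that(is_count(cfg$aggregate$min_species, 0L), "aggregate.min_species", "must be >= 0")
  check_that(is_real(cfg$aggregate$min_fraction, 0, 1), "aggregate.min_fraction", "must be in [0,1]")
  check_that(is_real(cfg$qc$exclude_z, 0), "qc.exclude_z", "must be >= 0")
  check_that(is_real(cfg$rda$vif_exclude, 1), "rda.vif_exclude", "must be >= 1")
  check_that(is_count(cfg$gapfill$rank), "gapfill.rank", "must be >= 1")
  check_that(is_count(cfg$seed, 0L), "seed", "must be a non-negative integer")
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration to JSON
#'
#' Round-trips through [validate_config()] unchanged.
#'
#' @param config a `run_config`.
#' @return JSON string.
#' @export
serialize_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null")
}

.log_msg <- function(cfg, ...) {
  if (isTRUE(cfg$verbosity >= 1)) message(sprintf(...))
}

#' Run the full trait-environment pipeline
#'
#' Executes gap-fill, z-score QC, A1/A2 aggregation, trait clustering and
#' PCA, latitudinal fits of the first two components, the climate/soil
#' variance partition, and the RDA, on synthetic or file inputs. All stage
#' seeds are spawned from `config$seed`. If `config$outdir` is set, stage
#' outputs and the report are written there as delimited text / JSON.
#'
#' @param config a `run_config` (or anything [validate_config()] accepts).
#' @return run report list.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- validate_config(config)
  seeds <- spawn_seeds(cfg$seed, 6L)

  # --- input stage
  if (cfg$mode == "synthetic") {
    wc <- do.call(world_config, modifyList(list(seed = seeds[1]), cfg$world))
    world <- simulate_world(wc)
    obs <- world$observations
    env <- world$environment
    eco <- world$ecoregions
    signed <- if (is.na(wc$signed_trait)) character(0) else wc$signed_trait
  } else {
    inp <- read_world(cfg$input_dir)
    obs <- inp$observations; env <- inp$environment; eco <- inp$ecoregions
    world <- NULL
    signed <- attr(obs, "signed_traits")
    if (is.null(signed)) signed <- character(0)
  }
  trait_cols <- attr(obs, "trait_cols")
  topsoil_cols <- attr(env, "topsoil_cols")
  climate_cols <- attr(env, "climate_cols")
  soil_cols <- attr(env, "soil_cols")

  # --- gap-fill (observation level, taxonomy-informed), then zlog QC
  m <- as.matrix(obs[, trait_cols])
  rownames(m) <- obs$species
  gap_report <- NULL
  if (anyNA(m) && isTRUE(cfg$gapfill$enabled)) {
    taxonomy <- unique(obs[, c("species", "genus", "family")])
    model <- hpmf_model(rank = cfg$gapfill$rank,
                        noise_precision = cfg$gapfill$noise_precision,
                        max_iter = cfg$gapfill$max_iter,
                        burn_in = cfg$gapfill$burn_in, thin = cfg$gapfill$thin,
                        patience = cfg$gapfill$patience,
                        stable_tol = cfg$gapfill$stable_tol, seed = seeds[2])
    .log_msg(cfg, "gap-filling %d missing cells", sum(is.na(m)))
    gf <- gapfill(m, taxonomy, model, signed_traits = signed)
    was_missing <- is.na(m)
    m <- gf$completed
    gap_report <- gf$report[c("n_draws", "stopped_early", "iterations")]
    gap_report$final_rmse_validation <- tail(gf$report$rmse_validation, 1)
  } else {
    was_missing <- is.na(m)
  }
  zl <- zlog(log_trait_matrix(m, signed_traits = signed))
  qc <- qc_filter(zl$z)
  drop_cells <- is.na(qc$z) & !is.na(zl$z)
  if (isTRUE(cfg$qc$filter_observed_only)) drop_cells <- drop_cells & !was_missing
  m[drop_cells] <- NA
  obs[, trait_cols] <- m

  # --- aggregation
  a1 <- species_medians(obs, trait_cols = trait_cols)
  em <- ecoregion_medians(a1, eco, min_species = cfg$aggregate$min_species,
                          min_fraction = cfg$aggregate$min_fraction,
                          trait_cols = trait_cols)
  a2 <- em$a2
  env_agg <- aggregate_environment(obs, env)
  env_agg <- env_agg[match(a2$ecoregion, env_agg$ecoregion), , drop = FALSE]
  eco_lat <- eco$latitude[match(a2$ecoregion, eco$ecoregion)]

  # --- trait structure on A1 (complete rows only)
  a1_traits <- as.matrix(a1[, trait_cols])
  complete <- stats::complete.cases(a1_traits)
  corr <- correlation_matrix(a1_traits[complete, , drop = FALSE],
                             signed_traits = signed)
  clus <- cluster_traits(corr, cut = cfg$axes$cut)
  pca <- pca_traits(a1_traits[complete, , drop = FALSE], signed_traits = signed)
  n_axes <- if (isTRUE(cfg$axes$run_permutation_test)) {
    significant_axes(a1_traits[complete, , drop = FALSE], n_perm = cfg$axes$n_perm,
                     alpha = cfg$axes$alpha, seed = seeds[3], signed_traits = signed)
  } else cfg$axes$n_axes
  lat1 <- latitude_fit(pca$scores[, 1], a1$latitude[complete])
  lat2 <- latitude_fit(pca$scores[, 2], a1$latitude[complete])

  # --- climate/soil partition on A2
  spec <- ridge_spec(n_lambda = cfg$partition$n_lambda,
                     inner_folds = cfg$partition$inner_folds,
                     outer_folds = cfg$partition$outer_folds,
                     repetitions = cfg$partition$repetitions,
                     block_size = cfg$partition$block_size, seed = seeds[4])
  a2_traits <- as.matrix(a2[, trait_cols])
  groups <- setNames(paste0("cluster", clus$groups), names(clus$groups))
  part <- partition_table(a2_traits, env_agg[, climate_cols, drop = FALSE],
                          env_agg[, soil_cols, drop = FALSE], spec,
                          groups = groups, signed_traits = signed)

  # --- RDA on A2 (climate + topsoil)
  soil_for_rda <- if (isTRUE(cfg$rda$topsoil_only) && !is.null(topsoil_cols)) {
    topsoil_cols
  } else soil_cols
  Xr <- scale(as.matrix(env_agg[, c(climate_cols, soil_for_rda), drop = FALSE]))
  pr <- vif_prune(Xr, exclude_above = cfg$rda$vif_exclude,
                  target_max = cfg$rda$vif_target)
  Yr <- scale(log_trait_matrix(a2_traits, signed_traits = signed))
  rda <- fit_rda(Yr, pr$X, scale_y = FALSE)

  report <- list(
    config = unclass(cfg),
    seeds = seeds,
    qc = list(excluded = sum(qc$report$n_excluded),
              flagged = sum(qc$report$n_flagged),
              per_trait = qc$report),
    gapfill = gap_report,
    a1_rows = nrow(a1),
    a2_rows = nrow(a2),
    excluded_ecoregions = em$exclusions,
    cluster_groups = clus$groups,
    pca_var_fraction = pca$var_fraction,
    n_significant_axes = n_axes,
    latitude = list(
      pc1 = list(species_r2 = lat1$species$r_squared, binned_r2 = lat1$binned$r_squared),
      pc2 = list(species_r2 = lat2$species$r_squared, binned_r2 = lat2$binned$r_squared)
    ),
    partition = part$table,
    rda = list(frac_total = rda$frac_total, frac_constrained = rda$frac_constrained,
               max_vif = pr$max_vif, n_predictors = ncol(pr$X))
  )
  result <- list(report = report, a1 = a1, a2 = a2, env_agg = env_agg,
                 pca = pca, cluster = clus, partition = part, rda = rda,
                 world = world)

  if (!is.na(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(a1, file.path(cfg$outdir, "a1_species_medians.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE, na = "")
    write.table(a2, file.path(cfg$outdir, "a2_ecoregion_medians.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE, na = "")
    write.table(part$table, file.path(cfg$outdir, "partition_table.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE, na = "")
    write.table(em$exclusions, file.path(cfg$outdir, "excluded_ecoregions.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE, na = "")
    jsonlite::write_json(
      report[setdiff(names(report), c("partition", "excluded_ecoregions"))],
      file.path(cfg$outdir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null", force = TRUE)
  }
  result
}
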