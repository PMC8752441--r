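# Synthetic world generator.
#
# The generator emits the same three delimited tables the real-data path
# consumes (observations, environment, ecoregion metadata), but from a known
# latent structure: one latitude-linked factor L drives the climate block and
# the whole-plant size axis, and a soil-side latent M = sqrt(w)*L +
# sqrt(1-w)*F (F an independent "fertility" factor, w = shared_latent_weight)
# drives the soil block and the leaf-economics axis. Every downstream stage
# (gap-fill, aggregation, trait axes, climate/soil partition, RDA) can then be
# tested against ground truth.

.default_traits_17 <- function() {
  data.frame(
    trait = c("seed_length", "dispersal_length", "seed_mass", "height",
              "leaf_fresh_mass", "leaf_area", "conduit_density",
              "stem_density", "leaf_C", "leaf_NP", "leaf_P", "leaf_N_area",
              "SLA", "leaf_N",
              "vessel_length", "leaf_d15N", "seeds_per_unit"),
    group = c(rep("size", 7), rep("economics", 7), rep("other", 3)),
    size_loading = c(0.9, 0.7, 1.0, 1.0, 0.8, 0.9, -0.8,
                     rep(0, 7), rep(0, 3)),
    econ_loading = c(rep(0, 7),
                     -0.45, 0.35, 0.55, 0.65, 0.45, 0.7, 0.65,
                     rep(0, 3)),
    stringsAsFactors = FALSE
  )
}

.default_traits_n <- function(n) {
  if (n == 17L) return(.default_traits_17())
  n_size <- max(1L, floor(n * 0.4))
  n_econ <- max(1L, floor(n * 0.4))
  n_other <- n - n_size - n_econ
  mags <- rep(c(1, 0.9, 0.8, 0.7, 0.6), length.out = n)
  data.frame(
    trait = sprintf("trait%02d", seq_len(n)),
    group = c(rep("size", n_size), rep("economics", n_econ), rep("other", max(0L, n_other))),
    size_loading = c(mags[seq_len(n_size)], rep(0, n - n_size)),
    econ_loading = c(rep(0, n_size), mags[seq_len(n_econ)], rep(0, max(0L, n_other))),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic trait-environment world
#'
#' Assembles and validates the parameters of the synthetic world. Traits
#' partition into "size", "economics" and "other" groups via their nonzero
#' loadings on the two latent axes. Defaults emulate the structure of the
#' global trait dataset the pipeline targets: 17 traits (7 size, 7 economics,
#' 3 weakly structured), 21 climate variables driven by a latitude-linked
#' factor, 107 soil variables tagged by depth layer (the 0 cm layer is the
#' "topsoil" subset used by the RDA filter), lognormal trait scales, and
#' heavy-tailed sampling effort across ecoregions emulating the Europe bias
#' of real trait archives.
#'
#' @param n_species number of species.
#' @param n_ecoregions number of ecoregions.
#' @param n_traits number of traits (default 17).
#' @param n_climate_vars number of climate variables (default 21).
#' @param n_soil_vars number of soil variables (default 107), assigned depth
#'   layers cycling through 0, 5, 15, 30, 60, 100, 200 cm.
#' @param shared_latent_weight fraction (in `[0,1]`) of soil-latent variance
#'   carried by the latitude-linked factor L.
#' @param size_loadings,econ_loadings per-trait loadings on the size and
#'   economics axes; defaults encode the 7/7/3 grouping.
#' @param trait_names trait names; must match loading lengths.
#' @param signed_trait name of the one trait generated on a signed linear
#'   scale (a leaf delta-15N analogue, exempt from log transformation), or
#'   `NA` for none.
#' @param trait_noise_sd residual sd of a single observation on the (natural
#'   log) trait scale.
#' @param taxonomy_sd sd of genus-level trait deviations (species-level
#'   deviations use half this value), giving taxonomically structured means.
#' @param score_noise_sd sd of species score noise around the latent factor
#'   of the species' home ecoregions.
#' @param climate_noise_sd,soil_noise_sd per-location environmental noise sd.
#' @param mean_occupancy mean number of ecoregions a species occupies
#'   (at least 1; 1 + Poisson(mean_occupancy - 1)).
#' @param mean_obs mean observations per (species, ecoregion) pair
#'   (1 + Poisson(mean_obs - 1)).
#' @param locations_per_ecoregion sampling locations per ecoregion.
#' @param missing_rate fraction of trait cells set to missing (in `[0,1)`).
#' @param seed integer seed; the whole world is reproducible from it.
#' @return a `world_config` list.
#' @export
world_config <- function(n_species = 400L, n_ecoregions = 50L, n_traits = 17L,
                         n_climate_vars = 21L, n_soil_vars = 107L,
                         shared_latent_weight = 0.5,
                         size_loadings = NULL, econ_loadings = NULL,
                         trait_names = NULL, signed_trait = NULL,
                         trait_noise_sd = 0.5, taxonomy_sd = 0.3,
                         score_noise_sd = 0.3,
                         climate_noise_sd = 0.3, soil_noise_sd = 0.3,
                         mean_occupancy = 3, mean_obs = 2,
                         locations_per_ecoregion = 3L,
                         missing_rate = 0, seed = 1L) {
  check_that(is_count(n_species), "n_species", "must be a count >= 1")
  check_that(is_count(n_ecoregions), "n_ecoregions", "must be a count >= 1")
  check_that(is_count(n_traits), "n_traits", "must be a count >= 1")
  check_that(is_count(n_climate_vars), "n_climate_vars", "must be a count >= 1")
  check_that(is_count(n_soil_vars), "n_soil_vars", "must be a count >= 1")
  check_that(is_real(shared_latent_weight, 0, 1), "shared_latent_weight", "must lie in [0, 1]")
  check_that(is_real(trait_noise_sd, 0), "trait_noise_sd", "must be >= 0")
  check_that(is_real(taxonomy_sd, 0), "taxonomy_sd", "must be >= 0")
  check_that(is_real(score_noise_sd, 0), "score_noise_sd", "must be >= 0")
  check_that(is_real(climate_noise_sd, 0), "climate_noise_sd", "must be >= 0")
  check_that(is_real(soil_noise_sd, 0), "soil_noise_sd", "must be >= 0")
  check_that(is_real(mean_occupancy, 1), "mean_occupancy", "must be >= 1")
  check_that(is_real(mean_obs, 1), "mean_obs", "must be >= 1")
  check_that(is_count(locations_per_ecoregion), "locations_per_ecoregion", "must be a count >= 1")
  check_that(is_real(missing_rate, 0) && missing_rate < 1, "missing_rate", "must lie in [0, 1)")
  check_that(is_count(seed, min = 0L), "seed", "must be a non-negative integer")

  defaults <- .default_traits_n(as.integer(n_traits))
  if (is.null(trait_names)) trait_names <- defaults$trait
  if (is.null(size_loadings)) size_loadings <- defaults$size_loading
  if (is.null(econ_loadings)) econ_loadings <- defaults$econ_loading
  check_that(length(trait_names) == n_traits, "trait_names", "length must equal n_traits")
  check_that(length(size_loadings) == n_traits && is.numeric(size_loadings),
             "size_loadings", "must be numeric of length n_traits")
  check_that(length(econ_loadings) == n_traits && is.numeric(econ_loadings),
             "econ_loadings", "must be numeric of length n_traits")
  check_that(!anyDuplicated(trait_names), "trait_names", "must be unique")
  if (is.null(signed_trait)) {
    signed_trait <- if ("leaf_d15N" %in% trait_names) "leaf_d15N" else NA_character_
  }
  if (!is.na(signed_trait)) {
    check_that(signed_trait %in% trait_names, "signed_trait", "must be one of trait_names")
  }

  structure(list(
    n_species = as.integer(n_species), n_ecoregions = as.integer(n_ecoregions),
    n_traits = as.integer(n_traits), n_climate_vars = as.integer(n_climate_vars),
    n_soil_vars = as.integer(n_soil_vars),
    shared_latent_weight = shared_latent_weight,
    trait_names = trait_names, size_loadings = size_loadings,
    econ_loadings = econ_loadings, signed_trait = signed_trait,
    trait_noise_sd = trait_noise_sd, taxonomy_sd = taxonomy_sd,
    score_noise_sd = score_noise_sd,
    climate_noise_sd = climate_noise_sd, soil_noise_sd = soil_noise_sd,
    mean_occupancy = mean_occupancy, mean_obs = mean_obs,
    locations_per_ecoregion = as.integer(locations_per_ecoregion),
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "world_config")
}

.soil_depths <- c(0L, 5L, 15L, 30L, 60L, 100L, 200L)

#' Simulate a synthetic trait-environment world
#'
#' Generates ecoregions on a latitudinal gradient, a taxonomy, species size
#' and economics scores tied to the latent factors of the ecoregions each
#' species occupies, per-observation trait values on a lognormal scale, and
#' location-level climate and soil variables. Climate variables are affine in
#' the latitude-linked factor L; soil variables are affine in
#' `M = sqrt(w) L + sqrt(1-w) F` with F independent of L.
#'
#' @param config a [world_config()].
#' @return a list of class `world` with elements `observations` (one row per
#'   trait observation; trait columns carry the `trait_cols` attribute),
#'   `environment` (one row per sampling location), `ecoregions` (metadata
#'   with richness estimates and biome labels), and `truth` (a `world_truth`
#'   object holding latent factors, species scores and generative loadings).
#' @export
simulate_world <- function(config) {
  if (!inherits(config, "world_config")) config <- do.call(world_config, config)
  set.seed(config$seed)
  ne <- config$n_ecoregions; ns <- config$n_species; nt <- config$n_traits

  # --- ecoregions: latitudes uniform on [0, 70] absolute, random hemisphere
  abs_lat <- runif(ne, 0, 70)
  hemi <- sample(c(-1, 1), ne, replace = TRUE)
  lat <- abs_lat * hemi
  # heavy-tailed sampling effort per ecoregion (Europe-bias analogue); drawn
  # first so the fertility factor can be orthogonalized against L under the
  # sampling distribution actually used for species placement
  eco_weight <- rlnorm(ne, 0, 1)
  # L is (minus) standardized absolute latitude: size declines poleward
  L <- if (ne > 1) as.numeric(scale(-abs_lat)) else 0
  F_ <- if (ne > 1) {
    f0 <- rnorm(ne)
    # fertility is latitude-independent: remove any sample correlation with
    # L, weighting by sampling effort so species-level scores inherit none
    as.numeric(scale(lm(f0 ~ L, weights = eco_weight)$residuals))
  } else 0
  w <- config$shared_latent_weight
  M <- sqrt(w) * L + sqrt(1 - w) * F_
  biome <- cut(abs_lat, breaks = c(-Inf, 23.5, 55, Inf),
               labels = c("tropical", "temperate", "boreal"))
  richness <- pmax(50L, round(rlnorm(ne, meanlog = log(2000), sdlog = 0.6)))
  eco_id <- sprintf("ER%03d", seq_len(ne))
  ecoregions <- data.frame(ecoregion = eco_id, biome = as.character(biome),
                           latitude = lat, richness_estimate = richness,
                           stringsAsFactors = FALSE)

  # --- sampling locations and environment
  nl <- config$locations_per_ecoregion
  loc_eco <- rep(seq_len(ne), each = nl)
  loc_id <- sprintf("L%05d", seq_along(loc_eco))
  loc_lat <- lat[loc_eco] + runif(length(loc_eco), -1, 1)
  loc_lon <- runif(length(loc_eco), -180, 180)
  climate_load <- sample(c(-1, 1), config$n_climate_vars, TRUE) *
    runif(config$n_climate_vars, 0.5, 1)
  soil_load <- sample(c(-1, 1), config$n_soil_vars, TRUE) *
    runif(config$n_soil_vars, 0.5, 1)
  clim <- outer(L[loc_eco], climate_load) +
    matrix(rnorm(length(loc_eco) * config$n_climate_vars, sd = config$climate_noise_sd),
           nrow = length(loc_eco))
  soil <- outer(M[loc_eco], soil_load) +
    matrix(rnorm(length(loc_eco) * config$n_soil_vars, sd = config$soil_noise_sd),
           nrow = length(loc_eco))
  climate_names <- sprintf("climate_%02d", seq_len(config$n_climate_vars))
  depth <- .soil_depths[((seq_len(config$n_soil_vars) - 1L) %% 7L) + 1L]
  prop <- ((seq_len(config$n_soil_vars) - 1L) %/% 7L) + 1L
  soil_names <- sprintf("soil_p%02d_d%03d", prop, depth)
  colnames(clim) <- climate_names
  colnames(soil) <- soil_names
  environment_tab <- data.frame(location_id = loc_id, ecoregion = eco_id[loc_eco],
                                clim, soil, check.names = FALSE,
                                stringsAsFactors = FALSE)
  attr(environment_tab, "climate_cols") <- climate_names
  attr(environment_tab, "soil_cols") <- soil_names
  attr(environment_tab, "topsoil_cols") <- soil_names[depth == 0L]

  # --- taxonomy
  n_gen <- max(1L, round(ns / 5))
  n_fam <- max(1L, round(n_gen / 4))
  sp_id <- sprintf("sp%04d", seq_len(ns))
  genus_of <- sample(seq_len(n_gen), ns, replace = TRUE)
  family_of_genus <- sample(seq_len(n_fam), n_gen, replace = TRUE)
  genus_id <- sprintf("gen%03d", genus_of)
  family_id <- sprintf("fam%03d", family_of_genus[genus_of])

  # --- occupancy: heavy-tailed ecoregion sampling weights (Europe-bias
  # analogue). Ranges are environmentally coherent: a species occupies its
  # home ecoregion plus ecoregions within a 10-degree absolute-latitude
  # window, preferring ecoregions whose soil-side latent resembles home
  # (species occur where both climate and soils suit them).
  home_of <- integer(ns)
  occ <- lapply(seq_len(ns), function(s) {
    home <- sample.int(ne, 1L, prob = eco_weight)
    home_of[s] <<- home
    k <- min(ne, 1L + rpois(1L, config$mean_occupancy - 1))
    cand <- setdiff(which(abs(abs_lat - abs_lat[home]) <= 10), home)
    extra <- if (length(cand) && k > 1L) {
      pr <- eco_weight[cand] * exp(-2 * (M[cand] - M[home])^2)
      cand[sample.int(length(cand), min(k - 1L, length(cand)), prob = pr)]
    } else integer(0)
    c(home, extra)
  })

  # --- species scores: size from the home ecoregion's latitude-linked
  # factor, economics from its soil-side latent
  size_score <- L[home_of] + rnorm(ns, sd = config$score_noise_sd)
  econ_score <- M[home_of] + rnorm(ns, sd = config$score_noise_sd)

  # --- taxonomically structured trait deviations
  gen_dev <- matrix(rnorm(n_gen * nt, sd = config$taxonomy_sd), n_gen, nt)
  sp_dev <- matrix(rnorm(ns * nt, sd = config$taxonomy_sd / 2), ns, nt)
  base <- seq(0.5, 1.5, length.out = nt)   # trait-specific intercepts (log scale)

  # --- observations
  pair_sp <- rep(seq_len(ns), lengths(occ))
  pair_eco <- unlist(occ)
  n_obs_pair <- 1L + rpois(length(pair_sp), config$mean_obs - 1)
  obs_sp <- rep(pair_sp, n_obs_pair)
  obs_eco <- rep(pair_eco, n_obs_pair)
  n_obs <- length(obs_sp)
  obs_loc_ix <- (obs_eco - 1L) * nl + sample.int(nl, n_obs, replace = TRUE)

  latent <- outer(size_score[obs_sp], config$size_loadings) +
    outer(econ_score[obs_sp], config$econ_loadings)
  log_vals <- sweep(latent, 2, base, "+") + gen_dev[genus_of[obs_sp], , drop = FALSE] +
    sp_dev[obs_sp, , drop = FALSE] +
    matrix(rnorm(n_obs * nt, sd = config$trait_noise_sd), n_obs, nt)
  vals <- exp(log_vals)
  if (!is.na(config$signed_trait)) {
    j <- match(config$signed_trait, config$trait_names)
    vals[, j] <- log_vals[, j] - base[j]   # signed linear scale, centred near 0
  }
  colnames(vals) <- config$trait_names

  observations <- data.frame(
    obs_id = sprintf("obs%06d", seq_len(n_obs)),
    species = sp_id[obs_sp], genus = genus_id[obs_sp], family = family_id[obs_sp],
    higher = "Plantae",
    ecoregion = eco_id[obs_eco], location_id = loc_id[obs_loc_ix],
    latitude = loc_lat[obs_loc_ix], longitude = loc_lon[obs_loc_ix],
    vals, check.names = FALSE, stringsAsFactors = FALSE
  )
  attr(observations, "trait_cols") <- config$trait_names

  truth <- structure(list(
    config = config,
    ecoregion = eco_id, latitude = lat, L = L, F = F_, M = M,
    species = sp_id, size_score = size_score, econ_score = econ_score,
    home_ecoregion = eco_id[home_of],
    genus = genus_id, family = family_id,
    climate_loadings = climate_load, soil_loadings = soil_load,
    soil_depth = depth
  ), class = "world_truth")

  if (config$missing_rate > 0) {
    observations <- inject_missingness(observations, config$missing_rate,
                                       seed = config$seed + 1L)
  }

  structure(list(observations = observations, environment = environment_tab,
                 ecoregions = ecoregions, truth = truth), class = "world")
}

#' Inject missing values into an observation table
#'
#' Sets approximately `rate` of the trait cells to `NA`, constrained so that
#' every observation row and every trait column keeps at least one observed
#' value (the minimum the hierarchical matrix-factorization gap-filler
#' requires). Deterministic under `seed`.
#'
#' @param obs observation table with trait columns (uses the `trait_cols`
#'   attribute, or `trait_cols` argument).
#' @param rate target missing fraction, in `[0, 1)`.
#' @param seed integer seed.
#' @param trait_cols trait column names.
#' @return the table with missing cells injected; `trait_cols` attribute kept.
#' @export
inject_missingness <- function(obs, rate, seed = 1L,
                               trait_cols = attr(obs, "trait_cols")) {
  if (!is_real(rate, 0) || rate >= 1) {
    stop("rate must lie in [0, 1): a rate of 1 would leave no observed value per row/column",
         call. = FALSE)
  }
  if (is.null(trait_cols)) stop("trait_cols not given and not an attribute of obs", call. = FALSE)
  if (rate == 0) return(obs)
  m <- as.matrix(obs[, trait_cols, drop = FALSE])
  observed <- which(!is.na(m))
  target <- round(rate * length(m))
  # necessary condition: at least max(rows, cols) observed cells must remain
  if (length(observed) - target < max(nrow(m), ncol(m))) {
    stop(sprintf("cannot remove %d of %d cells while keeping >=1 value per row and column",
                 target, length(m)), call. = FALSE)
  }
  set.seed(as.integer(seed))
  order_ix <- sample(observed)
  row_cnt <- rowSums(!is.na(m))
  col_cnt <- colSums(!is.na(m))
  removed <- 0L
  for (ix in order_ix) {
    if (removed >= target) break
    i <- ((ix - 1L) %% nrow(m)) + 1L
    j <- ((ix - 1L) %/% nrow(m)) + 1L
    if (row_cnt[i] > 1L && col_cnt[j] > 1L) {
      m[ix] <- NA
      row_cnt[i] <- row_cnt[i] - 1L
      col_cnt[j] <- col_cnt[j] - 1L
      removed <- removed + 1L
    }
  }
  obs[, trait_cols] <- m
  attr(obs, "trait_cols") <- trait_cols
  obs
}

#' Summarize the generative truth of a synthetic world
#'
#' Reports, per trait, its generative group and the environmental driver the
#' loadings imply, for use in recovery assertions: size traits are driven by
#' the latitude-linked climate factor ("climate"); economics traits are
#' driven by the soil-side latent, which is purely fertility ("soil-independent")
#' at `shared_latent_weight = 0`, purely the shared latitude factor ("joint")
#' at weight 1, and a mixture ("mixed") in between; unloaded traits are "none".
#'
#' @param truth a `world_truth` from [simulate_world()].
#' @return data.frame with columns trait, group, size_loading, econ_loading,
#'   expected_driver.
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "world_truth"))
  cfg <- truth$config
  w <- cfg$shared_latent_weight
  has_size <- cfg$size_loadings != 0
  has_econ <- cfg$econ_loadings != 0
  group <- ifelse(has_size & !has_econ, "size",
                  ifelse(has_econ & !has_size, "economics",
                         ifelse(has_size & has_econ, "mixed", "other")))
  econ_driver <- if (w == 0) "soil-independent" else if (w == 1) "joint" else "mixed"
  driver <- ifelse(has_size & has_econ, "joint",
                   ifelse(has_size, "climate",
                          ifelse(has_econ, econ_driver, "none")))
  data.frame(trait = cfg$trait_names, group = group,
             size_loading = cfg$size_loadings, econ_loading = cfg$econ_loadings,
             expected_driver = driver, stringsAsFactors = FALSE)
}

#' Write the synthetic world's tables as delimited text
#'
#' Writes `observations.tsv`, `environment.tsv` and `ecoregions.tsv`
#' (tab-delimited, missing values as empty fields) plus `schema.json`
#' documenting column roles, in the schema the file-input pipeline mode reads.
#'
#' @param world a `world` from [simulate_world()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("observations.tsv", "environment.tsv", "ecoregions.tsv"))
  write.table(world$observations, paths[1], sep = "\t", row.names = FALSE,
              quote = FALSE, na = "")
  write.table(world$environment, paths[2], sep = "\t", row.names = FALSE,
              quote = FALSE, na = "")
  write.table(world$ecoregions, paths[3], sep = "\t", row.names = FALSE,
              quote = FALSE, na = "")
  schema <- list(
    observations = list(id_cols = c("obs_id", "species", "genus", "family",
                                    "higher", "ecoregion", "location_id",
                                    "latitude", "longitude"),
                        trait_cols = attr(world$observations, "trait_cols"),
                        signed_traits = if (is.na(world$truth$config$signed_trait))
                          character(0) else world$truth$config$signed_trait),
    environment = list(id_cols = c("location_id", "ecoregion"),
                       climate_cols = attr(world$environment, "climate_cols"),
                       soil_cols = attr(world$environment, "soil_cols"),
                       topsoil_cols = attr(world$environment, "topsoil_cols")),
    ecoregions = list(cols = names(world$ecoregions))
  )
  schema_path <- file.path(dir, "schema.json")
  jsonlite::write_json(schema, schema_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, schema_path))
}

#' Read the three pipeline input tables from a directory
#'
#' Counterpart of [write_world()]: reads `observations.tsv`,
#' `environment.tsv`, `ecoregions.tsv` and `schema.json`, restoring the
#' column-role attributes.
#'
#' @param dir directory containing the tables.
#' @return list with `observations`, `environment`, `ecoregions`.
#' @export
read_world <- function(dir) {
  paths <- file.path(dir, c("observations.tsv", "environment.tsv",
                            "ecoregions.tsv", "schema.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(sprintf("input file not found: %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  schema <- jsonlite::read_json(paths[4], simplifyVector = TRUE)
  obs <- read.delim(paths[1], check.names = FALSE, na.strings = "",
                    stringsAsFactors = FALSE)
  env <- read.delim(paths[2], check.names = FALSE, na.strings = "",
                    stringsAsFactors = FALSE)
  eco <- read.delim(paths[3], check.names = FALSE, na.strings = "",
                    stringsAsFactors = FALSE)
  attr(obs, "trait_cols") <- schema$observations$trait_cols
  attr(obs, "signed_traits") <- as.character(schema$observations$signed_traits)
  attr(env, "climate_cols") <- schema$environment$climate_cols
  attr(env, "soil_cols") <- schema$environment$soil_cols
  attr(env, "topsoil_cols") <- schema$environment$topsoil_cols
  list(observations = obs, environment = env, ecoregions = eco)
}
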