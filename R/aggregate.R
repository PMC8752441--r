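# Aggregation of observations to species medians per ecoregion (A1) and
# ecoregion medians of species medians (A2), with the ecoregion inclusion
# filters (>20 species and >1% of estimated species richness), and
# observation-weighted aggregation of environmental variables.

#' Species-median trait values per ecoregion (A1)
#'
#' Collapses the observation table to one row per (species, ecoregion) pair:
#' the median of each trait's non-missing observations, a representative
#' latitude (mean of contributing observation latitudes), and the
#' observation count.
#'
#' @param obs observation table with columns `species`, `ecoregion`,
#'   `latitude` and trait columns (`trait_cols` attribute or argument).
#' @param trait_cols trait column names.
#' @return data.frame (A1) with one row per (species, ecoregion); trait
#'   medians keep the `trait_cols` attribute.
#' @export
species_medians <- function(obs, trait_cols = attr(obs, "trait_cols")) {
  if (is.null(trait_cols)) stop("trait_cols not given and not an attribute of obs", call. = FALSE)
  need <- c("species", "ecoregion", "latitude")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop(sprintf("obs lacks column(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  if (anyNA(obs$ecoregion)) {
    stop("observations without an ecoregion id are not allowed (non-georeferenced rows must be excluded upstream)",
         call. = FALSE)
  }
  dt <- data.table::as.data.table(obs[, c(need, trait_cols)])
  med <- function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  a1 <- dt[, c(list(latitude = mean(latitude), n_observations = .N),
               lapply(.SD, med)),
           by = c("species", "ecoregion"), .SDcols = trait_cols]
  data.table::setorder(a1, species, ecoregion)
  a1 <- as.data.frame(a1)
  attr(a1, "trait_cols") <- trait_cols
  a1
}

#' Ecoregion medians of species medians (A2) with inclusion filters
#'
#' Per ecoregion, takes the median over species medians for each trait and
#' applies the inclusion criteria: strictly more than `min_species` species
#' and strictly more than `min_fraction` of the ecoregion's estimated species
#' richness. Excluded ecoregions are reported with the criterion they failed.
#'
#' @param a1 output of [species_medians()].
#' @param richness data.frame with columns `ecoregion`, `richness_estimate`
#'   covering every candidate ecoregion.
#' @param min_species species-count threshold (default 20; rule is `>`).
#' @param min_fraction richness-fraction threshold (default 0.01; rule is `>`).
#' @param trait_cols trait column names.
#' @return list with `a2` (included ecoregions: trait medians, `n_species`,
#'   `richness_estimate`) and `exclusions` (ecoregion, criterion, value).
#' @export
ecoregion_medians <- function(a1, richness, min_species = 20L, min_fraction = 0.01,
                              trait_cols = attr(a1, "trait_cols")) {
  if (is.null(trait_cols)) stop("trait_cols not given and not an attribute of a1", call. = FALSE)
  dt <- data.table::as.data.table(a1[, c("species", "ecoregion", trait_cols)])
  med <- function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  agg <- dt[, c(list(n_species = data.table::uniqueN(species)),
                lapply(.SD, med)),
            by = "ecoregion", .SDcols = trait_cols]
  data.table::setorder(agg, ecoregion)
  agg <- as.data.frame(agg)
  ix <- match(agg$ecoregion, richness$ecoregion)
  if (anyNA(ix)) {
    stop(sprintf("no richness estimate for ecoregion '%s'", agg$ecoregion[which(is.na(ix))[1]]),
         call. = FALSE)
  }
  agg$richness_estimate <- richness$richness_estimate[ix]
  frac <- agg$n_species / agg$richness_estimate
  fail_n <- agg$n_species <= min_species
  fail_f <- frac <= min_fraction
  keep <- !(fail_n | fail_f)
  exclusions <- rbind(
    data.frame(ecoregion = agg$ecoregion[fail_n],
               criterion = rep("min_species", sum(fail_n)),
               value = agg$n_species[fail_n], stringsAsFactors = FALSE),
    data.frame(ecoregion = agg$ecoregion[fail_f],
               criterion = rep("min_fraction", sum(fail_f)),
               value = frac[fail_f], stringsAsFactors = FALSE)
  )
  a2 <- agg[keep, c("ecoregion", "n_species", "richness_estimate", trait_cols)]
  rownames(a2) <- NULL
  attr(a2, "trait_cols") <- trait_cols
  list(a2 = a2, exclusions = exclusions)
}

#' Observation-weighted ecoregion means of environmental variables
#'
#' Associates each trait observation with the environment of its sampling
#' location and averages within ecoregions, so densely sampled locations
#' weigh proportionally more (weighting "by the number and locations of
#' trait observations").
#'
#' @param obs observation table with columns `ecoregion`, `location_id` (one
#'   row per observation; duplicated locations count once per observation).
#' @param environment environment table with `location_id` and variable
#'   columns (any of the attributes `climate_cols`/`soil_cols`/`topsoil_cols`
#'   are propagated).
#' @param var_cols environment variable columns; defaults to all numeric
#'   non-id columns.
#' @return data.frame: one row per ecoregion present in `obs`, mean of each
#'   variable over observation-linked values.
#' @export
aggregate_environment <- function(obs, environment,
                                  var_cols = NULL) {
  if (is.null(var_cols)) {
    var_cols <- setdiff(names(environment), c("location_id", "ecoregion"))
  }
  ix <- match(obs$location_id, environment$location_id)
  if (anyNA(ix)) {
    stop(sprintf("no environment values for location '%s'",
                 obs$location_id[which(is.na(ix))[1]]), call. = FALSE)
  }
  linked <- data.table::as.data.table(environment[ix, var_cols, drop = FALSE])
  linked[, ecoregion := obs$ecoregion]
  out <- linked[, lapply(.SD, mean), by = "ecoregion", .SDcols = var_cols]
  data.table::setorder(out, ecoregion)
  out <- as.data.frame(out)
  for (a in c("climate_cols", "soil_cols", "topsoil_cols")) {
    if (!is.null(attr(environment, a))) attr(out, a) <- attr(environment, a)
  }
  out
}
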