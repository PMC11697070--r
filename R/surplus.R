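#' Soil-surface nitrogen surplus
#'
#' Computes the soil-surface N budget per unit and year:
#' `NS = FERT + MAN + DEP + BNF + STR - CROP`, all in kg ha-1 — fertiliser
#' application, manure returned to the field, atmospheric deposition,
#' biological fixation and straw return, minus crop N uptake. A negative
#' surplus (unit is a net N sink) is permitted and flagged with a warning,
#' not rejected.
#'
#' @param components data.frame with columns `unit_id`, `year`, `fert`,
#'   `man`, `dep`, `bnf`, `str`, `crop` (kg ha-1).
#' @return the input with an `ns` column (kg ha-1) appended.
#' @examples
#' compute_surplus(data.frame(unit_id = "U1", year = 2015, fert = 100,
#'                            man = 20, dep = 10, bnf = 5, str = 5, crop = 90))
#' @export
compute_surplus <- function(components) {
  comp <- c("fert", "man", "dep", "bnf", "str", "crop")
  validate_table(components, "budget", c("unit_id", "year", comp))
  for (nm in comp) {
    bad <- which(!is.finite(components[[nm]]))
    if (length(bad))
      stop_named("missing or non-finite component '%s' for unit %s (year %s)",
                 nm, components$unit_id[bad[1]], components$year[bad[1]])
    if (any(components[[nm]] < 0))
      stop_named("component '%s' must be non-negative", nm)
  }
  components$ns <- with(components, fert + man + dep + bnf + str - crop)
  if (any(components$ns < 0))
    warning(sprintf("%d unit-year(s) with negative N surplus (net sink); propagated, flagged",
                    sum(components$ns < 0)), call. = FALSE)
  components
}

#' Three-year average of budget components
#'
#' Averages each budget component over the window `center_year - 1` to
#' `center_year + 1` per unit, to mitigate interannual climate variability,
#' then recomputes the surplus. All three years must be present for every
#' unit.
#'
#' @param budgets budget table across years (components as in
#'   [compute_surplus()]).
#' @param center_year the year the average represents.
#' @return one row per unit with `year = center_year`, averaged components
#'   and recomputed `ns`.
#' @export
three_year_average <- function(budgets, center_year) {
  comp <- c("fert", "man", "dep", "bnf", "str", "crop")
  validate_table(budgets, "budget", c("unit_id", "year", comp))
  check_number(center_year, "center_year")
  want <- (center_year - 1):(center_year + 1)
  sub <- budgets[budgets$year %in% want, , drop = FALSE]
  counts <- table(sub$unit_id)
  units <- unique(budgets$unit_id)
  short <- units[!(units %in% names(counts)) | counts[units] < 3L]
  if (length(short))
    stop_named("unit '%s' is missing year(s) in %d-%d", short[1],
               want[1], want[3])
  means <- do.call(cbind, lapply(comp, function(nm)
    rowsum(sub[[nm]], sub$unit_id) / 3))
  colnames(means) <- comp
  out <- data.frame(unit_id = rownames(means), year = center_year,
                    means, row.names = NULL, stringsAsFactors = FALSE)
  suppressWarnings(compute_surplus(out))
}

#' Downscale unit-level surplus to grid cells
#'
#' Allocates each unit's surplus mass to its grid cells: the agricultural
#' surplus (`FERT + MAN + BNF + STR - CROP`, per unit hectare) is spread
#' equally per hectare across the unit's cropland cells; atmospheric
#' deposition is spread equally across its non-cropland cells. If a unit
#' has no non-cropland cells, deposition is added to cropland cells with a
#' warning (the mass must land somewhere); a unit with non-zero
#' agricultural surplus but no cropland cells is an error. Total mass is
#' conserved exactly per unit.
#'
#' @param budget one budget row per unit (with `ns` from
#'   [compute_surplus()] or [three_year_average()]).
#' @param cells grid table: `cell_id`, `unit_id`, `basin3_id`,
#'   `land_class` (`"cropland"` / `"non-cropland"`), `cell_area_ha`.
#' @return `cells` with `ns_kg_ha` (allocation rate) and `ns_kg`
#'   (cell mass) appended.
#' @export
downscale_surplus <- function(budget, cells) {
  comp <- c("fert", "man", "dep", "bnf", "str", "crop")
  validate_table(budget, "budget", c("unit_id", comp))
  validate_table(cells, "grid", c("cell_id", "unit_id", "basin3_id",
                                  "land_class", "cell_area_ha"))
  if (anyDuplicated(budget$unit_id))
    stop_named("'budget' must have one row per unit; duplicated unit ids")
  bad_cls <- setdiff(unique(cells$land_class), c("cropland", "non-cropland"))
  if (length(bad_cls))
    stop_named("unknown land_class value(s): %s", paste(bad_cls, collapse = ", "))
  orphan <- setdiff(unique(cells$unit_id), budget$unit_id)
  if (length(orphan))
    stop_named("grid references unit '%s' absent from the budget", orphan[1])

  i <- match(cells$unit_id, budget$unit_id)
  ag_rate <- with(budget, fert + man + bnf + str - crop)       # kg ha-1 of unit
  unit_area <- rowsum(cells$cell_area_ha, cells$unit_id)
  crop_area <- rowsum(cells$cell_area_ha * (cells$land_class == "cropland"),
                      cells$unit_id)
  ua <- unit_area[match(budget$unit_id, rownames(unit_area)), 1]
  ca <- crop_area[match(budget$unit_id, rownames(crop_area)), 1]
  if (any(is.na(ua) | ua <= 0))
    stop_named("unit '%s' has no grid cells",
               budget$unit_id[which(is.na(ua) | ua <= 0)[1]])
  nca <- ua - ca
  ag_mass <- ag_rate * ua
  dep_mass <- budget$dep * ua
  no_crop <- abs(ag_mass) > 0 & ca <= 0
  if (any(no_crop))
    stop_named("unit '%s' has agricultural surplus but no cropland cells; mass cannot be placed",
               budget$unit_id[which(no_crop)[1]])
  dep_to_crop <- nca <= 0
  if (any(dep_to_crop & dep_mass > 0))
    warning(sprintf("%d unit(s) have no non-cropland cells; deposition added to cropland",
                    sum(dep_to_crop & dep_mass > 0)), call. = FALSE)
  crop_rate <- ifelse(ca > 0,
                      (ag_mass + ifelse(dep_to_crop, dep_mass, 0)) / ca, 0)
  noncrop_rate <- ifelse(nca > 0, dep_mass / nca, 0)
  cells$ns_kg_ha <- ifelse(cells$land_class == "cropland",
                           crop_rate[i], noncrop_rate[i])
  cells$ns_kg <- cells$ns_kg_ha * cells$cell_area_ha
  cells
}

#' Aggregate cell surplus to third-order basins
#'
#' Area-weighted mean surplus per basin: total allocated mass over total
#' cell area, in kg ha-1 yr-1. Mass is conserved by construction. A basin
#' with zero cells is reported with `NA` and flagged.
#'
#' @param cell_surplus output of [downscale_surplus()].
#' @param basins optional basin table (`basin3_id`); basins absent from the
#'   grid are then included as flagged `NA` rows.
#' @return data.frame `basin3_id`, `area_ha`, `ns_kg`, `n_sur_kg_ha_yr`,
#'   `undefined`.
#' @export
basin_surplus <- function(cell_surplus, basins = NULL) {
  validate_table(cell_surplus, "cell_surplus",
                 c("basin3_id", "cell_area_ha", "ns_kg"))
  a <- rowsum(cell_surplus$cell_area_ha, cell_surplus$basin3_id)
  m <- rowsum(cell_surplus$ns_kg, cell_surplus$basin3_id)
  out <- data.frame(basin3_id = rownames(a), area_ha = a[, 1],
                    ns_kg = m[, 1], n_sur_kg_ha_yr = m[, 1] / a[, 1],
                    undefined = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(basins)) {
    validate_table(basins, "basins", "basin3_id")
    missing <- setdiff(basins$basin3_id, out$basin3_id)
    if (length(missing)) {
      out <- rbind(out, data.frame(basin3_id = missing, area_ha = 0,
                                   ns_kg = 0, n_sur_kg_ha_yr = NA_real_,
                                   undefined = TRUE))
      warning(sprintf("%d basin(s) have no grid cells; surplus undefined",
                      length(missing)), call. = FALSE)
    }
  }
  out[order(out$basin3_id), , drop = FALSE]
}

#' Basin nitrogen surplus for every snapshot epoch
#'
#' Convenience chain over the budget pipeline: three-year average around
#' each snapshot year, downscaling to the grid, and basin aggregation.
#'
#' @param budgets multi-year budget table.
#' @param cells grid table.
#' @param years snapshot years (default 1995, 2005, 2015).
#' @param basins optional basin table passed to [basin_surplus()].
#' @return data.frame `basin3_id`, `year`, `n_sur_kg_ha_yr`, `area_ha`.
#' @export
basin_surplus_by_epoch <- function(budgets, cells, years = c(1995, 2005, 2015),
                                   basins = NULL) {
  out <- lapply(years, function(yr) {
    avg <- three_year_average(budgets, yr)
    cs <- downscale_surplus(avg, cells)
    bs <- basin_surplus(cs, basins)
    data.frame(basin3_id = bs$basin3_id, year = yr,
               n_sur_kg_ha_yr = bs$n_sur_kg_ha_yr, area_ha = bs$area_ha,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
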