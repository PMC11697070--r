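#' Default nitrogen loss ratios per land-use class
#'
#' Fractions of the local N surplus mobilised towards surface water for the
#' four land-use classes entering the catchment delivery factor (paddy
#' fields, dryland agriculture, forest/grassland, constructed land). These
#' are representative magnitudes from the monitoring and modelling
#' literature on N loss in Chinese watersheds; treat them as configuration,
#' not measurements.
#'
#' @return named numeric vector over the four classes, values in \[0, 1\].
#' @export
default_loss_ratios <- function() {
  c(paddy = 0.35, dryland = 0.45, forest_grassland = 0.10, constructed = 0.25)
}

#' Default destination shares for lost small water bodies
#'
#' National-scale shares of small-water-body loss by destination land class
#' (cropland 49%, forest 19%, grassland 18%, constructed 7%, saline-alkali
#' 4%, other 3%), used by the synthetic generator when it converts a lost
#' body to another land cover.
#'
#' @return named numeric vector summing to 1.
#' @export
default_destination_shares <- function() {
  c(cropland = 0.49, forest = 0.19, grassland = 0.18,
    constructed = 0.07, `saline-alkali` = 0.04, other = 0.03)
}

#' Count-scale constant for a target inventory size
#'
#' Given the size-frequency exponent `d` and the sampled area range, return
#' the constant `c` of the binned power law `N_w = c * A^d` such that the
#' expected total number of bodies over half-decade bins equals `n_total`.
#'
#' @param n_total desired expected number of water bodies.
#' @param d power-law exponent (negative).
#' @param area_range_m2 \[min, max\] surface area range in m2.
#' @param bin_width width of the log10 bins (default 0.5, half decades).
#' @return the constant `c`.
#' @export
powerlaw_c_for_total <- function(n_total, d, area_range_m2, bin_width = 0.5) {
  check_number(n_total, "n_total", lower = 1)
  check_number(d, "d", upper = 0)
  check_range(area_range_m2, "area_range_m2")
  edges <- seq(log10(area_range_m2[1]), log10(area_range_m2[2]), by = bin_width)
  mids <- 10^((edges[-length(edges)] + edges[-1]) / 2)
  n_total / sum(mids^d)
}

#' Configuration for the synthetic landscape generator
#'
#' Bundles every knob of the synthetic landscape: the number of nested
#' basins, the truncated power-law size-frequency distribution of water
#' bodies, the per-decade preferential loss rate of small bodies, land-use
#' compositions, nutrient-budget component ranges and the temperature field.
#' Two presets mirror the study conditions: `"small"` is a desk-scale
#' landscape for tests and examples; `"national"` approximates the national
#' inventory (10 first-order basins, ~200 third-order basins, ~250,000
#' water bodies).
#'
#' @param preset `"small"` or `"national"`.
#' @param n_basins_first number of first-order basins.
#' @param n_basins_third_per_first third-order basins nested in each.
#' @param powerlaw_c count-scale constant of the binned law `N_w = c A^d`.
#' @param powerlaw_d size-frequency exponent (must be negative).
#' @param area_range_m2 \[min, max\] body surface area in m2.
#' @param small_loss_fraction_per_decade Bernoulli removal probability per
#'   decade for bodies below `10^4.5` m2 (bodies above are never removed).
#' @param landuse_dirichlet_weights Dirichlet concentration over the four
#'   delivery-factor land-use classes (paddy, dryland, forest/grassland,
#'   constructed).
#' @param destination_shares categorical distribution of destination land
#'   classes for lost bodies.
#' @param surplus_component_ranges named list of \[min, max\] ranges
#'   (kg ha-1) for the budget components fert, man, dep, bnf, str, crop.
#' @param temp_range_c \[min, max\] annual mean air temperature (deg C).
#' @param basin_water_ratio_range \[min, max\] ratio of basin land area to
#'   its total water surface area (log-uniform draw per basin).
#' @param cells_per_basin grid cells tiling each third-order basin.
#' @param seed integer root seed; all stages derive substreams from it.
#' @return an object of class `landscape_config` (a validated list).
#' @seealso [generate_landscape()]
#' @export
landscape_config <- function(preset = c("small", "national"),
                             n_basins_first = NULL,
                             n_basins_third_per_first = NULL,
                             powerlaw_c = NULL,
                             powerlaw_d = -0.8,
                             area_range_m2 = c(10^2.5, 10^7),
                             small_loss_fraction_per_decade = 0.3,
                             landuse_dirichlet_weights = c(paddy = 2, dryland = 4,
                                                           forest_grassland = 3,
                                                           constructed = 1),
                             destination_shares = default_destination_shares(),
                             surplus_component_ranges = list(
                               fert = c(50, 250), man = c(10, 80),
                               dep = c(10, 40), bnf = c(5, 25),
                               str = c(5, 30), crop = c(50, 200)),
                             temp_range_c = c(4, 22),
                             basin_water_ratio_range = c(10, 300),
                             cells_per_basin = 20L,
                             seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(n_basins_first))
    n_basins_first <- if (preset == "national") 10L else 3L
  if (is.null(n_basins_third_per_first))
    n_basins_third_per_first <- if (preset == "national") 20L else 5L
  check_number(powerlaw_d, "powerlaw_d", allow_na = FALSE)
  if (powerlaw_d >= 0) stop_named("'powerlaw_d' must be negative, got %g", powerlaw_d)
  if (is.null(powerlaw_c))
    powerlaw_c <- powerlaw_c_for_total(
      if (preset == "national") 250000 else 12000, powerlaw_d, area_range_m2)

  check_number(n_basins_first, "n_basins_first", lower = 1)
  check_number(n_basins_third_per_first, "n_basins_third_per_first", lower = 1)
  check_number(powerlaw_c, "powerlaw_c", lower = .Machine$double.xmin)
  check_number(powerlaw_d, "powerlaw_d")
  if (powerlaw_d >= 0) stop_named("'powerlaw_d' must be negative, got %g", powerlaw_d)
  check_range(area_range_m2, "area_range_m2")
  if (area_range_m2[1] <= 0) stop_named("'area_range_m2' min must be positive")
  check_number(small_loss_fraction_per_decade, "small_loss_fraction_per_decade",
               lower = 0, upper = 1)
  if (length(landuse_dirichlet_weights) != 4L || any(landuse_dirichlet_weights <= 0))
    stop_named("'landuse_dirichlet_weights' must be 4 positive weights")
  if (is.null(names(landuse_dirichlet_weights)))
    names(landuse_dirichlet_weights) <- GAMMA_LANDUSE_CLASSES
  if (abs(sum(destination_shares) - 1) > 1e-9)
    stop_named("'destination_shares' must sum to 1")
  bad_dest <- setdiff(names(destination_shares), DESTINATION_CLASSES)
  if (length(bad_dest))
    stop_named("'destination_shares' has unknown class(es): %s",
               paste(bad_dest, collapse = ", "))
  comp_names <- c("fert", "man", "dep", "bnf", "str", "crop")
  if (!setequal(names(surplus_component_ranges), comp_names))
    stop_named("'surplus_component_ranges' must name exactly: %s",
               paste(comp_names, collapse = ", "))
  for (nm in comp_names) {
    check_range(surplus_component_ranges[[nm]],
                paste0("surplus_component_ranges$", nm))
    if (surplus_component_ranges[[nm]][1] < 0)
      stop_named("'surplus_component_ranges$%s' must be non-negative", nm)
  }
  check_range(temp_range_c, "temp_range_c")
  check_range(basin_water_ratio_range, "basin_water_ratio_range")
  if (basin_water_ratio_range[1] <= 1)
    stop_named("'basin_water_ratio_range' min must exceed 1 (land > water)")
  check_number(cells_per_basin, "cells_per_basin", lower = 2)
  check_number(seed, "seed")

  structure(list(
    preset = preset,
    n_basins_first = as.integer(n_basins_first),
    n_basins_third_per_first = as.integer(n_basins_third_per_first),
    powerlaw_c = powerlaw_c,
    powerlaw_d = powerlaw_d,
    area_range_m2 = area_range_m2,
    small_loss_fraction_per_decade = small_loss_fraction_per_decade,
    landuse_dirichlet_weights = landuse_dirichlet_weights,
    destination_shares = destination_shares,
    surplus_component_ranges = surplus_component_ranges,
    temp_range_c = temp_range_c,
    basin_water_ratio_range = basin_water_ratio_range,
    cells_per_basin = as.integer(cells_per_basin),
    seed = as.integer(seed)
  ), class = "landscape_config")
}

#' @export
print.landscape_config <- function(x, ...) {
  cat("Synthetic landscape configuration (preset:", x$preset, ")\n")
  cat(sprintf("  basins: %d first-order x %d third-order each\n",
              x$n_basins_first, x$n_basins_third_per_first))
  cat(sprintf("  size-frequency law: N_w = %.4g * A^%.3g on [1e%.2g, 1e%.2g] m2\n",
              x$powerlaw_c, x$powerlaw_d,
              log10(x$area_range_m2[1]), log10(x$area_range_m2[2])))
  cat(sprintf("  small-body loss per decade: %.0f%%  seed: %d\n",
              100 * x$small_loss_fraction_per_decade, x$seed))
  invisible(x)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Accepts a file holding any subset of [landscape_config()] arguments plus
#' the optional run-level keys `n_draws`, `ns_threshold_kg_ha`,
#' `threshold_m2` and an `econ` block of [valuation()] arguments. Unknown
#' keys are an error so typos never pass silently.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a list with elements `landscape` (a `landscape_config`),
#'   `n_draws`, `ns_threshold_kg_ha`, `threshold_m2`, `econ`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_named("config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  run_keys <- c("n_draws", "ns_threshold_kg_ha", "threshold_m2", "econ")
  ls_keys <- setdiff(names(formals(landscape_config)), "preset")
  unknown <- setdiff(names(raw), c(run_keys, ls_keys, "preset"))
  if (length(unknown))
    stop_named("config file '%s' has unknown key(s): %s", path,
               paste(unknown, collapse = ", "))
  ls_args <- raw[intersect(names(raw), c("preset", ls_keys))]
  for (nm in intersect(names(ls_args), c("area_range_m2", "temp_range_c",
                                          "basin_water_ratio_range",
                                          "landuse_dirichlet_weights",
                                          "destination_shares")))
    ls_args[[nm]] <- unlist(ls_args[[nm]])
  if (!is.null(ls_args$surplus_component_ranges))
    ls_args$surplus_component_ranges <-
      lapply(ls_args$surplus_component_ranges, unlist)
  list(landscape = do.call(landscape_config, ls_args),
       n_draws = if (is.null(raw$n_draws)) 1000L else as.integer(raw$n_draws),
       ns_threshold_kg_ha = if (is.null(raw$ns_threshold_kg_ha)) 17
                            else raw$ns_threshold_kg_ha,
       threshold_m2 = if (is.null(raw$threshold_m2)) SMALL_BODY_THRESHOLD_M2
                      else raw$threshold_m2,
       econ = raw$econ)
}
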