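#' Generate a seeded synthetic landscape
#'
#' Builds a complete synthetic study region with the statistical structure
#' the downstream analysis assumes, so every stage of the pipeline runs
#' without any external data:
#'
#' * water-body surface areas drawn from a bounded Pareto whose binned
#'   counts follow the target power law `N_w = c A^d` by construction;
#' * three inventory snapshots (1995, 2005, 2015) with preferential loss:
#'   each decade, bodies below `10^4.5` m2 are removed independently with
#'   probability `small_loss_fraction_per_decade`, bodies above never are;
#' * each lost body converted to a destination land class drawn from the
#'   configured categorical distribution;
#' * nested basins (third-order within first-order) with Dirichlet land-use
#'   compositions and a basin-area-to-water-area ratio drawn log-uniformly;
#' * prefecture-like nutrient budgets (one unit per third-order basin) with
#'   the six soil-surface budget components per year, including the two
#'   neighbouring years of each snapshot for three-year averaging, and a
#'   per-unit multiplicative input trend across decades;
#' * a grid of cells per basin, classified cropland / non-cropland in
#'   proportion to the basin's land use, for budget downscaling;
#' * an annual mean temperature per basin, jittered per body.
#'
#' All randomness derives from `config$seed` via fixed substreams, so the
#' same configuration always yields identical tables.
#'
#' @param config a [landscape_config()].
#' @return an object of class `swb_landscape`: a list with data.frames
#'   `bodies` (id, year, area_m2, basin3_id, basin1_id, temp_c), `basins`
#'   (basin3_id, basin1_id, area_ha, f_paddy, f_dryland, f_forest_grassland,
#'   f_constructed, temp_c), `budgets` (unit_id, year, fert, man, dep, bnf,
#'   str, crop), `grid` (cell_id, basin3_id, unit_id, land_class,
#'   cell_area_ha), `transitions` (body_id, from_year, to_year,
#'   destination_class, area_m2, basin3_id, basin1_id), plus the `config`.
#' @examples
#' ls <- generate_landscape(landscape_config(seed = 42))
#' ls
#' @export
generate_landscape <- function(config) {
  if (!inherits(config, "landscape_config"))
    stop_named("'config' must be a landscape_config object")
  snap_years <- c(1995L, 2005L, 2015L)

  ## --- basins -------------------------------------------------------------
  set.seed(substream_seed(config$seed, 1L))
  n1 <- config$n_basins_first
  n3 <- config$n_basins_third_per_first
  basin1_id <- sprintf("B%02d", seq_len(n1))
  basins <- data.frame(
    basin3_id = sprintf("%s_%02d", rep(basin1_id, each = n3),
                        rep(seq_len(n3), n1)),
    basin1_id = rep(basin1_id, each = n3),
    stringsAsFactors = FALSE
  )
  nb <- nrow(basins)
  # Dirichlet land-use composition via normalised gammas
  w <- config$landuse_dirichlet_weights
  g <- matrix(stats::rgamma(nb * 4L, shape = rep(w, each = nb)), nrow = nb)
  f <- g / rowSums(g)
  basins$f_paddy <- f[, 1]; basins$f_dryland <- f[, 2]
  basins$f_forest_grassland <- f[, 3]; basins$f_constructed <- f[, 4]
  t1 <- stats::runif(n1, config$temp_range_c[1], config$temp_range_c[2])
  basins$temp_c <- pmin(pmax(rep(t1, each = n3) + stats::rnorm(nb, 0, 1),
                             config$temp_range_c[1] - 2),
                        config$temp_range_c[2] + 2)
  ratio <- exp(stats::runif(nb, log(config$basin_water_ratio_range[1]),
                            log(config$basin_water_ratio_range[2])))

  ## --- first snapshot: bounded-Pareto areas -------------------------------
  set.seed(substream_seed(config$seed, 2L))
  edges <- seq(log10(config$area_range_m2[1]), log10(config$area_range_m2[2]),
               by = 0.5)
  mids <- 10^((edges[-length(edges)] + edges[-1]) / 2)
  n_bodies <- max(1L, round(config$powerlaw_c * sum(mids^config$powerlaw_d)))
  a <- -config$powerlaw_d          # Pareto shape: pdf ~ x^(-a-1), bins ~ x^d
  L <- config$area_range_m2[1]; H <- config$area_range_m2[2]
  u <- stats::runif(n_bodies)
  area <- L / (1 - u * (1 - (L / H)^a))^(1 / a)
  b3 <- sample(basins$basin3_id, n_bodies, replace = TRUE)
  idx <- match(b3, basins$basin3_id)
  bodies0 <- data.frame(
    id = sprintf("W%07d", seq_len(n_bodies)),
    year = snap_years[1],
    area_m2 = area,
    basin3_id = b3,
    basin1_id = basins$basin1_id[idx],
    temp_c = basins$temp_c[idx] + stats::rnorm(n_bodies, 0, 0.5),
    stringsAsFactors = FALSE
  )

  # basin land area anchored to first-snapshot water area
  water_ha <- rep(0, nb)
  agg <- rowsum(bodies0$area_m2, bodies0$basin3_id) / 1e4
  water_ha[match(rownames(agg), basins$basin3_id)] <- agg[, 1]
  basins$area_ha <- pmax(water_ha, 1) * ratio

  ## --- later snapshots: preferential small-body loss ----------------------
  p <- config$small_loss_fraction_per_decade
  dest_classes <- names(config$destination_shares)
  snapshots <- list(bodies0)
  transitions <- list()
  current <- bodies0
  for (s in 2:3) {
    set.seed(substream_seed(config$seed, 2L + s))
    small <- current$area_m2 < SMALL_BODY_THRESHOLD_M2
    lost <- small & (stats::runif(nrow(current)) < p)
    if (any(lost)) {
      transitions[[s - 1L]] <- data.frame(
        body_id = current$id[lost],
        from_year = snap_years[s - 1L],
        to_year = snap_years[s],
        destination_class = sample(dest_classes, sum(lost), replace = TRUE,
                                   prob = config$destination_shares),
        area_m2 = current$area_m2[lost],
        basin3_id = current$basin3_id[lost],
        basin1_id = current$basin1_id[lost],
        stringsAsFactors = FALSE
      )
    }
    current <- current[!lost, , drop = FALSE]
    current$year <- snap_years[s]
    rownames(current) <- NULL
    snapshots[[s]] <- current
  }
  bodies <- do.call(rbind, snapshots)
  rownames(bodies) <- NULL
  transitions <- if (length(transitions)) do.call(rbind, transitions)
    else data.frame(body_id = character(), from_year = integer(),
                    to_year = integer(), destination_class = character(),
                    area_m2 = numeric(), basin3_id = character(),
                    basin1_id = character(), stringsAsFactors = FALSE)
  rownames(transitions) <- NULL

  ## --- grid cells ---------------------------------------------------------
  set.seed(substream_seed(config$seed, 6L))
  nc <- config$cells_per_basin
  f_crop <- basins$f_paddy + basins$f_dryland
  n_crop <- pmin(pmax(round(nc * f_crop), 1L), nc - 1L)
  grid <- data.frame(
    cell_id = sprintf("%s_c%03d", rep(basins$basin3_id, each = nc),
                      rep(seq_len(nc), nb)),
    basin3_id = rep(basins$basin3_id, each = nc),
    unit_id = rep(basins$basin3_id, each = nc),
    land_class = unlist(lapply(seq_len(nb), function(i)
      c(rep("cropland", n_crop[i]), rep("non-cropland", nc - n_crop[i])))),
    cell_area_ha = rep(basins$area_ha / nc, each = nc),
    stringsAsFactors = FALSE
  )

  ## --- nutrient budgets ---------------------------------------------------
  set.seed(substream_seed(config$seed, 7L))
  rng <- config$surplus_component_ranges
  comp_names <- c("fert", "man", "dep", "bnf", "str", "crop")
  base_rates <- vapply(comp_names, function(nm)
    stats::runif(nb, rng[[nm]][1], rng[[nm]][2]), numeric(nb))
  trend <- stats::runif(nb, 0.85, 1.25)   # per-decade input multiplier
  years <- as.vector(outer(-1:1, snap_years, `+`))
  rows <- vector("list", length(years))
  for (j in seq_along(years)) {
    yr <- years[j]
    epoch <- findInterval(yr, c(1990, 2000, 2010)) - 1L   # 0, 1, 2
    noise <- matrix(1 + stats::rnorm(nb * 6L, 0, 0.05), nrow = nb)
    m <- base_rates * noise
    m[, 1] <- m[, 1] * trend^epoch   # fert
    m[, 2] <- m[, 2] * trend^epoch   # man
    m <- pmax(m, 0)
    rows[[j]] <- data.frame(unit_id = basins$basin3_id, year = yr,
                            fert = m[, 1], man = m[, 2], dep = m[, 3],
                            bnf = m[, 4], str = m[, 5], crop = m[, 6],
                            stringsAsFactors = FALSE)
  }
  budgets <- do.call(rbind, rows)
  budgets <- budgets[order(budgets$unit_id, budgets$year), ]
  rownames(budgets) <- NULL

  structure(list(bodies = bodies, basins = basins, budgets = budgets,
                 grid = grid, transitions = transitions, config = config,
                 snapshot_years = snap_years),
            class = "swb_landscape")
}

#' @export
print.swb_landscape <- function(x, ...) {
  counts <- table(x$bodies$year)
  cat("Synthetic lentic landscape\n")
  cat(sprintf("  %d third-order basins in %d first-order basins\n",
              nrow(x$basins), length(unique(x$basins$basin1_id))))
  cat("  bodies per snapshot:",
      paste(sprintf("%s: %d", names(counts), counts), collapse = ", "), "\n")
  cat(sprintf("  lost small bodies recorded: %d\n", nrow(x$transitions)))
  invisible(x)
}

#' Extract one inventory snapshot
#'
#' @param landscape a `swb_landscape`.
#' @param year snapshot year (default: latest).
#' @return the `bodies` rows for that year.
#' @export
snapshot <- function(landscape, year = NULL) {
  if (!inherits(landscape, "swb_landscape"))
    stop_named("'landscape' must be a swb_landscape")
  if (is.null(year)) year <- max(landscape$bodies$year)
  out <- landscape$bodies[landscape$bodies$year == year, , drop = FALSE]
  if (!nrow(out)) stop_named("no snapshot for year %s", year)
  rownames(out) <- NULL
  out
}
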