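write_stage_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full nitrogen-retention pipeline
#'
#' Orchestrates every stage in dependency order on a synthetic landscape:
#' generation, size-binned inventory statistics and loss pathways,
#' power-law fits and fractal deficits (per first-order basin and pooled),
#' the nutrient-budget chain (three-year averages, downscaling, basin
#' aggregation), deterministic and Monte Carlo removal estimates, risk
#' classification, the three restoration scenarios, and the economic
#' valuation. All tabular artifacts are written as plain UTF-8 CSV with a
#' header row, summaries as JSON; every output directory carries a resolved
#' copy of the configuration stamped with its hash. Rerunning with the same
#' configuration and seed reproduces every output byte for byte.
#'
#' @param config a [landscape_config()], or the list returned by
#'   [read_pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file writing and just returns the artifacts.
#' @param n_draws Monte Carlo ensemble size (default from config or 1000).
#' @param seed overrides the config seed when given.
#' @param econ named list of [valuation()] arguments.
#' @param quiet suppress the per-stage log.
#' @return (invisibly) a list with every intermediate artifact:
#'   `landscape`, `dists`, `changes`, `shares`, `fits`, `deficits`,
#'   `basin_nitrogen`, `body_removal`, `mc`, `risk`, `scenarios`,
#'   `scenario_result`, `valuation`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_draws = NULL, seed = NULL,
                         econ = NULL, quiet = FALSE) {
  if (inherits(config, "landscape_config"))
    config <- list(landscape = config, n_draws = 1000L,
                   ns_threshold_kg_ha = 17,
                   threshold_m2 = SMALL_BODY_THRESHOLD_M2, econ = econ)
  ls_cfg <- config$landscape
  if (!inherits(ls_cfg, "landscape_config"))
    stop_named("'config' must be a landscape_config or read_pipeline_config() list")
  if (!is.null(seed)) ls_cfg$seed <- as.integer(seed)
  if (is.null(n_draws)) n_draws <- config$n_draws
  econ <- if (!is.null(econ)) econ else config$econ
  thr <- config$threshold_m2
  cfg_hash <- fnv1a(paste(utils::capture.output(utils::str(ls_cfg)),
                          collapse = "\n"))
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    dt <- proc.time()[["elapsed"]] - t0
    n <- if (is.data.frame(val)) nrow(val) else NA_integer_
    log[[name]] <<- data.frame(stage = name, seconds = round(dt, 3),
                               records = n)
    if (!quiet)
      message(sprintf("[%s] %.2fs%s", name, dt,
                      if (is.na(n)) "" else sprintf(" (%d records)", n)))
    val
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, file) {
    if (!is.null(out_dir)) write_stage_csv(df, file.path(out_dir, file))
    df
  }

  ## generate ---------------------------------------------------------------
  land <- stage("generate", generate_landscape(ls_cfg))
  emit(land$bodies, "bodies.csv"); emit(land$basins, "basins.csv")
  emit(land$budgets, "budget.csv"); emit(land$grid, "grid.csv")
  emit(land$transitions, "transitions.csv")
  years <- land$snapshot_years

  ## inventory --------------------------------------------------------------
  la <- log10(range(land$bodies$area_m2))
  edges <- seq(floor(la[1] / 0.5) * 0.5, floor(la[2] / 0.5) * 0.5 + 0.5,
               by = 0.5)
  dists <- stage("inventory", {
    lapply(stats::setNames(years, years), function(yr)
      bin_inventory(snapshot(land, yr), edges = edges))
  })
  dist_rows <- do.call(rbind, lapply(names(dists), function(yr)
    cbind(year = yr, as.data.frame(dists[[yr]]))))
  emit(dist_rows, "size_distribution.csv")
  changes <- Map(function(a, b) change_stats(dists[[a]], dists[[b]]),
                 utils::head(as.character(years), -1),
                 as.character(years)[-1])
  emit(do.call(rbind, lapply(names(changes), function(p)
    cbind(period = p, changes[[p]]$per_bin))), "change_stats.csv")
  shares <- transition_shares(land$transitions)
  emit(shares, "transition_shares.csv")

  ## fractal fits and deficits ----------------------------------------------
  current <- snapshot(land, max(years))
  fits <- stage("fit-powerlaw", {
    by_b1 <- split(current, current$basin1_id)
    f <- lapply(by_b1, function(b) tryCatch(
      fit_power_law(bin_inventory(b, edges = edges), threshold_m2 = thr),
      error = function(e) {
        warning(sprintf("basin %s: %s", b$basin1_id[1], conditionMessage(e)),
                call. = FALSE); NULL
      }))
    f$national <- fit_power_law(bin_inventory(current, edges = edges),
                                threshold_m2 = thr)
    f
  })
  deficits <- lapply(names(fits)[names(fits) != "national"], function(b1) {
    if (is.null(fits[[b1]])) return(NULL)
    fractal_deficit(bin_inventory(current[current$basin1_id == b1, ],
                                  edges = edges), fits[[b1]])
  })
  names(deficits) <- names(fits)[names(fits) != "national"]
  deficits <- Filter(Negate(is.null), deficits)
  emit(do.call(rbind, lapply(names(deficits), function(b1)
    cbind(basin1_id = b1, as.data.frame(deficits[[b1]])))), "deficit.csv")
  if (!is.null(out_dir)) {
    fit_json <- lapply(Filter(Negate(is.null), fits), function(f)
      f[c("c", "d", "r_squared", "p_value", "n_bins_used", "threshold_m2")])
    jsonlite::write_json(fit_json, file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## nitrogen surplus -------------------------------------------------------
  basin_n_epochs <- stage("surplus",
    basin_surplus_by_epoch(land$budgets, land$grid, years, land$basins))
  emit(basin_n_epochs, "basin_nitrogen.csv")
  avg <- three_year_average(land$budgets, max(years))
  cell_surplus <- downscale_surplus(avg, land$grid)
  emit(cell_surplus, "cell_surplus.csv")
  basin_n <- basin_n_epochs[basin_n_epochs$year == max(years), ]

  ## removal ----------------------------------------------------------------
  body_rem <- stage("removal",
    body_removal_table(current, land$basins, basin_n))
  emit(body_rem, "body_removal.csv")
  mc <- monte_carlo_removal(current, land$basins, basin_n, n_draws = n_draws,
                            seed = substream_seed(ls_cfg$seed, 20L))
  emit(mc$per_basin, "basin_removal.csv")
  rates <- class_areal_rates(body_rem, thr)
  if (!is.null(out_dir))
    jsonlite::write_json(
      c(mc$national, list(n_draws = mc$n_draws,
                          class_areal_rates = rates)),
      file.path(out_dir, "national_summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")

  ## risk -------------------------------------------------------------------
  risk <- stage("risk", classify_risk(basin_n_epochs, land$bodies,
                                      ns_threshold = config$ns_threshold_kg_ha,
                                      threshold_m2 = thr))
  emit(risk, "risk.csv")

  ## restoration scenarios --------------------------------------------------
  specs <- combine_scenarios(lapply(names(deficits), function(b1)
    suppressMessages(build_scenarios(deficits[[b1]], b1))))
  scen <- stage("restore",
    evaluate_scenarios(specs, current, land$basins, basin_n,
                       n_draws = n_draws,
                       seed = substream_seed(ls_cfg$seed, 21L)))
  emit(scen$summary, "scenario_results.csv")
  if (!is.null(out_dir))
    jsonlite::write_json(
      list(total_restore_area_m2 = attr(specs, "total_restore_area_m2"),
           restored_bodies = {
             tb <- table(specs$scenario)
             stats::setNames(as.list(as.integer(tb)), names(tb))
           }),
      file.path(out_dir, "scenarios.json"), auto_unbox = TRUE, digits = NA)

  ## economics --------------------------------------------------------------
  val <- stage("econ", do.call(valuation,
    c(list(r_awet_kg_yr = mc$national$median_kg_yr), econ)))
  if (!is.null(out_dir)) {
    jsonlite::write_json(as.list(val), file.path(out_dir, "valuation.json"),
                         auto_unbox = TRUE, digits = NA)
    resolved <- ls_cfg
    class(resolved) <- NULL
    jsonlite::write_json(list(config_hash = cfg_hash, n_draws = n_draws,
                              threshold_m2 = thr,
                              ns_threshold_kg_ha = config$ns_threshold_kg_ha,
                              landscape = resolved),
                         file.path(out_dir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(landscape = land, dists = dists, changes = changes,
                 shares = shares, fits = fits, deficits = deficits,
                 basin_nitrogen = basin_n_epochs, body_removal = body_rem,
                 mc = mc, class_areal_rates = rates, risk = risk,
                 scenarios = specs, scenario_result = scen, valuation = val,
                 config_hash = cfg_hash, log = do.call(rbind, log)))
}
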