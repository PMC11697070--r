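#' Classify basins by water-quality risk
#'
#' Four-way risk quadrants per third-order basin, combining the nitrogen
#' surplus with small-water-body (SWB) dynamics across epochs:
#'
#' * **current high risk** — latest-epoch N surplus above the threshold
#'   (default 17 kg ha-1 yr-1, the global average surplus) AND SWB area
#'   declining;
#' * **future high risk** — N surplus increasing across epochs AND SWB
#'   area declining;
#' * **both** — the intersection, basins already polluted whose pollutant
#'   sources grow while their filters disappear.
#'
#' Trends use strict inequalities; a basin with exactly zero change is not
#' at risk. Basins lacking two epochs of either series, or with a zero
#' baseline (percent change undefined), are flagged unclassifiable.
#'
#' @param basin_n_epochs basin N surplus per epoch (`basin3_id`, `year`,
#'   `n_sur_kg_ha_yr`), e.g. from [basin_surplus_by_epoch()].
#' @param bodies inventory rows across snapshot years.
#' @param ns_threshold surplus threshold, kg ha-1 yr-1 (default 17).
#' @param threshold_m2 small-body area threshold.
#' @return data.frame, one row per basin: `basin3_id`, `ns_level`,
#'   `ns_trend_pct`, `swb_area_trend_pct`, `current_high`, `future_high`,
#'   `both`, `unclassifiable`, `risk_class` in
#'   `{"both", "current", "future", "low", "unclassifiable"}`.
#' @export
classify_risk <- function(basin_n_epochs, bodies, ns_threshold = 17,
                          threshold_m2 = SMALL_BODY_THRESHOLD_M2) {
  validate_table(basin_n_epochs, "basin_nitrogen",
                 c("basin3_id", "year", "n_sur_kg_ha_yr"))
  check_number(ns_threshold, "ns_threshold")
  swb <- swb_area_by_basin(bodies, threshold_m2)
  ids <- sort(unique(c(basin_n_epochs$basin3_id, swb$basin3_id)))
  pct <- function(first, last) {
    if (is.na(first) || is.na(last) || first == 0) NA_real_
    else 100 * (last - first) / abs(first)
  }
  rows <- lapply(ids, function(b) {
    ns <- basin_n_epochs[basin_n_epochs$basin3_id == b, , drop = FALSE]
    ns <- ns[order(ns$year), ]
    sa <- swb[swb$basin3_id == b, , drop = FALSE]
    sa <- sa[order(sa$year), ]
    ok <- nrow(ns) >= 2L && all(is.finite(ns$n_sur_kg_ha_yr)) &&
          nrow(sa) >= 2L
    ns_level <- if (nrow(ns)) ns$n_sur_kg_ha_yr[nrow(ns)] else NA_real_
    ns_trend <- if (ok) pct(ns$n_sur_kg_ha_yr[1], ns$n_sur_kg_ha_yr[nrow(ns)])
                else NA_real_
    swb_trend <- if (ok) pct(sa$swb_area_m2[1], sa$swb_area_m2[nrow(sa)])
                 else NA_real_
    unclass <- !ok || is.na(ns_trend) || is.na(swb_trend) || is.na(ns_level)
    cur <- !unclass && ns_level > ns_threshold && swb_trend < 0
    fut <- !unclass && ns_trend > 0 && swb_trend < 0
    data.frame(basin3_id = b, ns_level = ns_level, ns_trend_pct = ns_trend,
               swb_area_trend_pct = swb_trend, current_high = cur,
               future_high = fut, both = cur && fut,
               unclassifiable = unclass,
               risk_class = if (unclass) "unclassifiable"
                            else if (cur && fut) "both"
                            else if (cur) "current"
                            else if (fut) "future" else "low",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count basins per risk class
#'
#' @param risk a [classify_risk()] result.
#' @return named integer vector over
#'   `both`, `current`, `future`, `low`, `unclassifiable` plus the marginal
#'   counts `current_high_total` and `future_high_total`.
#' @export
risk_counts <- function(risk) {
  validate_table(risk, "risk", c("risk_class", "current_high", "future_high"))
  lev <- c("both", "current", "future", "low", "unclassifiable")
  n <- vapply(lev, function(l) sum(risk$risk_class == l), integer(1))
  c(n, current_high_total = sum(risk$current_high),
    future_high_total = sum(risk$future_high))
}
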