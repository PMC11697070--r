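#' Bin a water-body inventory into half-decade size classes
#'
#' Groups bodies into half-open bins `[lo, hi)` of width 0.5 in log10
#' surface area (…, 10^2.5–10^3, 10^3–10^3.5, …), the classes used for all
#' size-dependent trend and power-law analysis. Edge bins are extended so
#' every body is covered. log10 areas are rounded to 9 decimals before
#' binning so a body of exactly `10^3` m2 lands in `[10^3, 10^3.5)`.
#'
#' @param bodies data.frame with columns `id` and `area_m2` (positive).
#' @param edges optional explicit log10(m2) bin edges (strictly increasing,
#'   multiples of `bin_width`); supply these to compare two snapshots on a
#'   common grid.
#' @param bin_width log10 bin width (default 0.5).
#' @return object of class `swb_size_dist`: a data.frame with one row per
#'   bin (`log10_lo`, `log10_hi`, `lo_m2`, `hi_m2`, `rep_area_m2` the
#'   geometric midpoint, `count`, `area_m2`).
#' @export
bin_inventory <- function(bodies, edges = NULL, bin_width = 0.5) {
  validate_table(bodies, "bodies", c("id", "area_m2"))
  if (!nrow(bodies)) stop_named("'bodies' is empty; nothing to bin")
  bad <- which(!is.finite(bodies$area_m2) | bodies$area_m2 <= 0)
  if (length(bad))
    stop_named("non-positive or non-finite area for body id(s): %s",
               paste(utils::head(bodies$id[bad], 5L), collapse = ", "))
  la <- round(log10(bodies$area_m2), 9)
  if (is.null(edges)) {
    lo <- floor(min(la) / bin_width) * bin_width
    hi <- floor(max(la) / bin_width) * bin_width + bin_width
    edges <- seq(lo, hi, by = bin_width)
  } else {
    if (any(diff(edges) <= 0)) stop_named("'edges' must be strictly increasing")
    if (min(la) < edges[1] || max(la) >= edges[length(edges)])
      stop_named("'edges' [%g, %g] do not cover the data range [%g, %g]",
                 edges[1], edges[length(edges)], min(la), max(la))
  }
  k <- findInterval(la, edges)            # half-open [edge_i, edge_{i+1})
  nbin <- length(edges) - 1L
  count <- tabulate(k, nbins = nbin)
  area <- rep(0, nbin)
  sums <- rowsum(bodies$area_m2, k)
  area[as.integer(rownames(sums))] <- sums[, 1]
  out <- data.frame(
    log10_lo = edges[-length(edges)],
    log10_hi = edges[-1],
    lo_m2 = 10^edges[-length(edges)],
    hi_m2 = 10^edges[-1],
    rep_area_m2 = 10^((edges[-length(edges)] + edges[-1]) / 2),
    count = count,
    area_m2 = area
  )
  structure(out, class = c("swb_size_dist", "data.frame"),
            n_bodies = nrow(bodies), bin_width = bin_width)
}

#' Per-bin change between two size distributions
#'
#' Percent change in count and total area per size class between two
#' snapshots binned on identical edges, plus inventory-wide totals. A bin
#' with zero baseline is flagged `undefined` and reported as `NA`, never as
#' an infinite percentage.
#'
#' @param dist_a,dist_b `swb_size_dist` objects on identical edges
#'   (`dist_a` is the baseline).
#' @return list with `per_bin` (data.frame: bin columns,
#'   `count_change_pct`, `area_change_pct`, `undefined`) and `totals`
#'   (named vector: `count_change_pct`, `area_change_pct`).
#' @export
change_stats <- function(dist_a, dist_b) {
  if (!inherits(dist_a, "swb_size_dist") || !inherits(dist_b, "swb_size_dist"))
    stop_named("both arguments must be swb_size_dist objects")
  if (nrow(dist_a) != nrow(dist_b) ||
      any(abs(dist_a$log10_lo - dist_b$log10_lo) > 1e-12))
    stop_named("bin edges differ: a = [%s], b = [%s]",
               paste(signif(c(dist_a$log10_lo, dist_a$log10_hi[nrow(dist_a)]), 4),
                     collapse = ", "),
               paste(signif(c(dist_b$log10_lo, dist_b$log10_hi[nrow(dist_b)]), 4),
                     collapse = ", "))
  pct <- function(a, b) ifelse(a == 0, NA_real_, 100 * (b - a) / a)
  per_bin <- data.frame(
    log10_lo = dist_a$log10_lo, log10_hi = dist_a$log10_hi,
    rep_area_m2 = dist_a$rep_area_m2,
    count_a = dist_a$count, count_b = dist_b$count,
    count_change_pct = pct(dist_a$count, dist_b$count),
    area_change_pct = pct(dist_a$area_m2, dist_b$area_m2),
    undefined = dist_a$count == 0
  )
  totals <- c(count_change_pct = unname(pct(sum(dist_a$count), sum(dist_b$count))),
              area_change_pct = unname(pct(sum(dist_a$area_m2), sum(dist_b$area_m2))))
  list(per_bin = per_bin, totals = totals)
}

#' Loss-pathway shares of converted small water bodies
#'
#' Fractions of lost small-water-body count and area per destination land
#' class, nationally or per first-order basin.
#'
#' @param transitions data.frame with `body_id`, `destination_class`,
#'   `area_m2` and, for `by = "basin1"`, `basin1_id`.
#' @param by `"national"` (default) or `"basin1"`.
#' @return data.frame with `group`, `destination_class`, `n`,
#'   `count_share`, `area_share`; zero rows for an empty transition set.
#' @export
transition_shares <- function(transitions, by = c("national", "basin1")) {
  by <- match.arg(by)
  cols <- c("body_id", "destination_class", "area_m2",
            if (by == "basin1") "basin1_id")
  validate_table(transitions, "transitions", cols)
  empty <- data.frame(group = character(), destination_class = character(),
                      n = integer(), count_share = numeric(),
                      area_share = numeric(), stringsAsFactors = FALSE)
  if (!nrow(transitions)) return(empty)
  bad <- setdiff(unique(transitions$destination_class), DESTINATION_CLASSES)
  if (length(bad))
    stop_named("unknown destination class(es): %s", paste(bad, collapse = ", "))
  grp <- if (by == "national") rep("national", nrow(transitions))
         else transitions$basin1_id
  res <- lapply(split(seq_len(nrow(transitions)), grp), function(ix) {
    n <- tapply(rep(1L, length(ix)), transitions$destination_class[ix], sum)
    a <- tapply(transitions$area_m2[ix], transitions$destination_class[ix], sum)
    data.frame(destination_class = names(n), n = as.integer(n),
               count_share = as.numeric(n) / length(ix),
               area_share = as.numeric(a) / sum(transitions$area_m2[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Map(function(g, df) cbind(group = g, df),
                            names(res), res))
  rownames(out) <- NULL
  out
}

#' Total small-water-body area per basin and snapshot year
#'
#' @param bodies inventory rows across snapshots (`year`, `area_m2`,
#'   `basin3_id`).
#' @param threshold_m2 small-body threshold (default `10^4.5`).
#' @return data.frame `basin3_id`, `year`, `swb_area_m2`, `swb_count`
#'   (complete over the basin x year cross, zeros where none).
#' @export
swb_area_by_basin <- function(bodies, threshold_m2 = SMALL_BODY_THRESHOLD_M2) {
  validate_table(bodies, "bodies", c("year", "area_m2", "basin3_id"))
  sm <- bodies[bodies$area_m2 < threshold_m2, , drop = FALSE]
  out <- expand.grid(basin3_id = unique(bodies$basin3_id),
                     year = sort(unique(bodies$year)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(sm$basin3_id, sm$year)
  a <- rowsum(sm$area_m2, key)
  n <- rowsum(rep(1L, nrow(sm)), key)
  m <- match(paste(out$basin3_id, out$year), rownames(a))
  out$swb_area_m2 <- ifelse(is.na(m), 0, a[m, 1])
  out$swb_count <- ifelse(is.na(m), 0L, n[m, 1])
  out
}
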