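#' Build the three equal-area restoration scenarios
#'
#' From the fractal deficit of a first-order basin, constructs three
#' restoration designs of identical total area:
#'
#' * **S1** — restore the fractal distribution: the per-bin deficit counts
#'   (rounded to whole bodies) at the bins' geometric-midpoint areas, all
#'   below the small-body threshold;
#' * **S2** — the same total area as ten water bodies of equal size;
#' * **S3** — the same total area as one very large water body.
#'
#' The shared total is the S1 total (integer counts times representative
#' areas), so the equal-area contract holds exactly. A deficit that rounds
#' to zero bodies yields an empty specification.
#'
#' @param deficit a [fractal_deficit()] result for the basin.
#' @param basin1_id identifier of the first-order basin.
#' @return object of class `swb_scenarios`: data.frame with one row per
#'   restored body (`scenario`, `basin1_id`, `body_area_m2`) and attribute
#'   `total_restore_area_m2`.
#' @export
build_scenarios <- function(deficit, basin1_id) {
  if (!inherits(deficit, "swb_fractal_deficit"))
    stop_named("'deficit' must be a swb_fractal_deficit")
  counts <- round(deficit$deficit_count)
  sizes <- rep(deficit$rep_area_m2, counts)
  empty <- data.frame(scenario = character(), basin1_id = character(),
                      body_area_m2 = numeric(), stringsAsFactors = FALSE)
  if (!length(sizes)) {
    message(sprintf("basin %s: zero fractal deficit; empty scenario set",
                    basin1_id))
    return(structure(empty, class = c("swb_scenarios", "data.frame"),
                     total_restore_area_m2 = 0))
  }
  total <- sum(sizes)
  out <- rbind(
    data.frame(scenario = "S1", basin1_id = basin1_id, body_area_m2 = sizes,
               stringsAsFactors = FALSE),
    data.frame(scenario = "S2", basin1_id = basin1_id,
               body_area_m2 = rep(total / 10, 10), stringsAsFactors = FALSE),
    data.frame(scenario = "S3", basin1_id = basin1_id, body_area_m2 = total,
               stringsAsFactors = FALSE)
  )
  structure(out, class = c("swb_scenarios", "data.frame"),
            total_restore_area_m2 = total)
}

#' Combine per-basin scenario specifications
#'
#' @param ... `swb_scenarios` objects (or a single list of them).
#' @return one `swb_scenarios` spanning all basins; the total-area
#'   attribute is the sum.
#' @export
combine_scenarios <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1]], "swb_scenarios"))
    specs <- specs[[1]]
  stopifnot(all(vapply(specs, inherits, logical(1), "swb_scenarios")))
  out <- do.call(rbind, lapply(specs, as.data.frame))
  rownames(out) <- NULL
  structure(out, class = c("swb_scenarios", "data.frame"),
            total_restore_area_m2 =
              sum(vapply(specs, attr, numeric(1), "total_restore_area_m2")))
}

#' Evaluate restoration scenarios by Monte Carlo
#'
#' Adds the restored bodies of each scenario to the landscape and
#' re-evaluates national nitrogen removal per Monte Carlo draw, against the
#' same draw's baseline (paired draws), folding two sources of uncertainty
#' into one ensemble:
#'
#' * **parameters** — delivery factor and watershed-area ratio drawn per
#'   basin per draw exactly as in [monte_carlo_removal()];
#' * **location** — S1 bodies inherit temperature and basin (hence N
#'   surplus) from a donor sampled among the existing small bodies of their
#'   first-order basin (joint sampling: one donor gives both); S2/S3 bodies
#'   are placed uniformly at random in one of the first-order basin's
#'   third-order basins, inheriting that basin's temperature and surplus.
#'
#' Restored bodies participate in the contributing-area rescaling of the
#' basin they land in, so dense basins saturate rather than overdraw.
#'
#' @param specs a `swb_scenarios` (possibly combined across basins).
#' @param bodies the current (baseline) inventory snapshot.
#' @param basins basin table (must include `temp_c`).
#' @param basin_n basin N surplus table; every basin must have a defined
#'   surplus (restored bodies may land anywhere).
#' @param n_draws,seed ensemble size and seed.
#' @param alpha_gmean,alpha_gsd,alpha_range,gamma_range,gamma_cv,loss_ratios
#'   as in [monte_carlo_removal()].
#' @return object of class `swb_scenario_result`: list with `summary`
#'   (data.frame per scenario: `median_increase_pct`, `q25/q75`,
#'   `median_increase_kg_yr`, `restored_area_m2`), `draws_pct` (matrix
#'   draws x scenarios), `per_basin1` (median percent increase per
#'   first-order basin and scenario), `baseline_median_kg_yr`.
#' @export
evaluate_scenarios <- function(specs, bodies, basins, basin_n,
                               n_draws = 1000L, seed = 1L,
                               alpha_gmean = sqrt(3 * 20), alpha_gsd = 1.6,
                               alpha_range = c(3, 20),
                               gamma_range = c(0.3, 0.5), gamma_cv = 0.25,
                               loss_ratios = default_loss_ratios()) {
  if (!inherits(specs, "swb_scenarios"))
    stop_named("'specs' must be a swb_scenarios object")
  validate_table(basins, "basins", c("basin3_id", "basin1_id", "temp_c"))
  check_number(n_draws, "n_draws", lower = 1)
  terms <- basin_terms(bodies, basins, basin_n, loss_ratios)
  # restored bodies may be placed in any basin: surplus must be defined
  j <- match(basins$basin3_id, basin_n$basin3_id)
  if (anyNA(j) || anyNA(basin_n$n_sur_kg_ha_yr[j]))
    stop_named("basin '%s' has undefined N surplus; restored bodies cannot be placed",
               basins$basin3_id[which(is.na(j) | is.na(basin_n$n_sur_kg_ha_yr[j]))[1]])
  nb <- nrow(terms)
  scen_names <- c("S1", "S2", "S3")
  b1_levels <- sort(unique(terms$basin1_id))
  b1_of_basin <- match(terms$basin1_id, b1_levels)
  basins_by_b1 <- split(seq_len(nb), terms$basin1_id)

  # donor pools: existing small bodies per first-order basin
  body_basin_idx <- match(bodies$basin3_id, terms$basin3_id)
  small <- bodies$area_m2 < SMALL_BODY_THRESHOLD_M2
  donors_by_b1 <- split(which(small), terms$basin1_id[body_basin_idx[small]])

  spec_by_scen <- lapply(scen_names, function(s)
    specs[specs$scenario == s, , drop = FALSE])
  names(spec_by_scen) <- scen_names
  need_donors <- unique(spec_by_scen$S1$basin1_id)
  no_pool <- setdiff(need_donors, names(donors_by_b1))
  if (length(no_pool))
    stop_named("first-order basin '%s' has no existing small bodies to sample donors from",
               no_pool[1])

  set.seed(as.integer(seed))
  inc_pct <- matrix(NA_real_, n_draws, 3L,
                    dimnames = list(NULL, scen_names))
  inc_kg <- inc_pct
  base_draws <- numeric(n_draws)
  pb1 <- array(NA_real_, c(n_draws, length(b1_levels), 3L),
               dimnames = list(NULL, b1_levels, scen_names))

  for (dd in seq_len(n_draws)) {
    gam <- rnorm_trunc(nb, terms$gamma_mean, gamma_cv * terms$gamma_mean,
                       gamma_range[1], gamma_range[2])
    alp <- rlnorm_trunc(nb, log(alpha_gmean), log(alpha_gsd),
                        alpha_range[1], alpha_range[2])
    base_b <- basin_totals(terms, gam, alp)
    base_draws[dd] <- sum(base_b)
    base_g <- rowsum(base_b, b1_of_basin)

    for (s in scen_names) {
      sp <- spec_by_scen[[s]]
      if (!nrow(sp)) {
        inc_pct[dd, s] <- 0; inc_kg[dd, s] <- 0
        pb1[dd, , s] <- 0
        next
      }
      # placement draw: basin index + temperature per restored body
      if (s == "S1") {
        donor <- unlist(lapply(split(seq_len(nrow(sp)), sp$basin1_id),
          function(ix) {
            pool <- donors_by_b1[[sp$basin1_id[ix[1]]]]
            pool[sample.int(length(pool), length(ix), replace = TRUE)]
          }), use.names = FALSE)
        ridx <- unlist(split(seq_len(nrow(sp)), sp$basin1_id),
                       use.names = FALSE)
        bidx <- body_basin_idx[donor]
        rtemp <- bodies$temp_c[donor]
        rarea <- sp$body_area_m2[ridx]
      } else {
        bidx <- unlist(lapply(split(seq_len(nrow(sp)), sp$basin1_id),
          function(ix) {
            memb <- basins_by_b1[[sp$basin1_id[ix[1]]]]
            memb[sample.int(length(memb), length(ix), replace = TRUE)]
          }), use.names = FALSE)
        ridx <- unlist(split(seq_len(nrow(sp)), sp$basin1_id),
                       use.names = FALSE)
        rtemp <- basins$temp_c[match(terms$basin3_id[bidx], basins$basin3_id)]
        rarea <- sp$body_area_m2[ridx]
      }
      rho <- removal_efficiency(rarea, rtemp)$rho_percent
      sa_ha <- rarea / 1e4
      S_rest <- numeric(nb); W_rest <- numeric(nb)
      tmpS <- rowsum(sa_ha, bidx); tmpW <- rowsum(sa_ha * rho, bidx)
      S_rest[as.integer(rownames(tmpS))] <- tmpS[, 1]
      W_rest[as.integer(rownames(tmpW))] <- tmpW[, 1]
      S_tot <- terms$S_ha + S_rest
      scale2 <- ifelse(S_tot > 0, pmin(1, terms$area_ha / (alp * S_tot)), 1)
      with_b <- gam * terms$n_sur * alp * scale2 * (terms$Wrho + W_rest) / 100
      inc_kg[dd, s] <- sum(with_b) - sum(base_b)
      inc_pct[dd, s] <- 100 * inc_kg[dd, s] / sum(base_b)
      with_g <- rowsum(with_b, b1_of_basin)
      pb1[dd, , s] <- 100 * (with_g - base_g) / base_g
    }
  }

  totals_by_b1 <- vapply(scen_names, function(s) {
    sp <- spec_by_scen[[s]]
    sum(sp$body_area_m2)
  }, numeric(1))
  q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  summ <- do.call(rbind, lapply(scen_names, function(s) {
    qp <- q(inc_pct[, s]); qk <- q(inc_kg[, s])
    data.frame(scenario = s, restored_area_m2 = totals_by_b1[[s]],
               median_increase_pct = qp[2], q25_pct = qp[1], q75_pct = qp[3],
               median_increase_kg_yr = qk[2], q25_kg_yr = qk[1],
               q75_kg_yr = qk[3], stringsAsFactors = FALSE)
  }))
  per_b1 <- apply(pb1, c(2, 3), stats::median)
  structure(list(summary = summ, draws_pct = inc_pct, draws_kg_yr = inc_kg,
                 per_basin1_median_pct = per_b1,
                 baseline_median_kg_yr = stats::median(base_draws),
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "swb_scenario_result")
}

#' @export
print.swb_scenario_result <- function(x, ...) {
  cat(sprintf("Restoration scenario ensemble (%d draws)\n", x$n_draws))
  cat(sprintf("  baseline national removal (median): %.4g kg yr-1\n",
              x$baseline_median_kg_yr))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %s: +%.1f%% [IQR %.1f-%.1f] (%.3g kg yr-1; restored %.3g ha)\n",
                s$scenario, s$median_increase_pct, s$q25_pct, s$q75_pct,
                s$median_increase_kg_yr, s$restored_area_m2 / 1e4))
  }
  invisible(x)
}
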