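#' Per-body nitrogen removal efficiency (HydroBio-k)
#'
#' First-order denitrification kinetics driven by hydraulic residence time
#' and temperature. Residence time scales with surface area,
#' `tau = 1.66 * SA^0.24` (days, SA in m2); the rate constant follows
#' `ln k = -1.07 ln(tau) + 0.29 * Tc - 0.5` with the temperature factor
#' `Tc = (temp - 20) / 10`; removal efficiency is
#' `rho = (1 - exp(-k * tau)) * 100` percent. Because `k * tau` decreases
#' with surface area, small bodies remove a larger fraction of their
#' incoming nitrogen — the mechanism that makes small-water-body
#' restoration efficient.
#'
#' @param sa_m2 surface area(s), m2, positive.
#' @param temp_c annual mean air temperature(s), deg C.
#' @return data.frame `sa_m2`, `temp_c`, `tau_days`, `k_per_day`, `t_c`,
#'   `rho_percent`.
#' @examples
#' removal_efficiency(10^4.5, 20)  # tau ~ 20 d, rho ~ 39%
#' @export
removal_efficiency <- function(sa_m2, temp_c) {
  if (!is.numeric(sa_m2) || any(!is.finite(sa_m2)) || any(sa_m2 <= 0))
    stop_named("'sa_m2' must be positive and finite")
  if (!is.numeric(temp_c) || any(!is.finite(temp_c)))
    stop_named("'temp_c' must be finite")
  n <- max(length(sa_m2), length(temp_c))
  sa <- rep_len(sa_m2, n); tc <- (rep_len(temp_c, n) - 20) / 10
  tau <- 1.66 * sa^0.24
  k <- exp(-1.07 * log(tau) + 0.29 * tc - 0.5)
  data.frame(sa_m2 = sa, temp_c = rep_len(temp_c, n), tau_days = tau,
             k_per_day = k, t_c = tc, rho_percent = (1 - exp(-k * tau)) * 100)
}

#' Catchment delivery factor from land-use composition
#'
#' The fraction of a basin's N surplus that reaches its water bodies rather
#' than being retained in soil or groundwater or denitrified upland.
#' Land-use fractions over paddy fields, dryland, forest/grassland and
#' constructed land are weighted by class-specific N loss ratios and the
#' weighted sum is normalised onto \[0.3, 0.5\]:
#' `gamma = (sum f_i * LR_i) * 0.2 + 0.3`.
#'
#' @param f land-use fractions (length 4, summing to 1 within 1e-8).
#' @param lr loss ratios per class, each in \[0, 1\].
#' @return the delivery factor, a number in \[0.3, 0.5\].
#' @examples
#' gamma_reduction(c(0.5, 0.5, 0, 0), c(0.4, 0.2, 0, 0))  # 0.36
#' @export
gamma_reduction <- function(f, lr) {
  if (length(f) != length(lr))
    stop_named("'f' and 'lr' must have equal length")
  if (any(!is.finite(f)) || any(f < 0))
    stop_named("'f' must be non-negative and finite")
  if (abs(sum(f) - 1) > 1e-8)
    stop_named("land-use fractions must sum to 1, got %.10g", sum(f))
  if (any(!is.finite(lr)) || any(lr < 0 | lr > 1))
    stop_named("loss ratios must lie in [0, 1]")
  sum(f * lr) * 0.2 + 0.3
}

#' Contributing areas with basin rescaling
#'
#' Each body drains a contributing area `CA = alpha * SA` (converted to
#' hectares). Where water bodies are dense the naive contributing areas can
#' exceed the basin itself; in that case all CAs are rescaled by a common
#' factor so their sum equals the basin area exactly — the nitrogen mass
#' entering water bodies can never exceed the mass available in the basin.
#'
#' @param sa_m2 body surface areas in m2.
#' @param alpha watershed-to-water-body area ratio, in \[3, 20\].
#' @param basin_area_ha basin area in hectares.
#' @return numeric vector of contributing areas (ha); `sum(CA) <=
#'   basin_area_ha` always, with equality when rescaling triggered.
#' @export
contributing_areas <- function(sa_m2, alpha, basin_area_ha) {
  check_number(alpha, "alpha", lower = 3, upper = 20)
  check_number(basin_area_ha, "basin_area_ha", lower = .Machine$double.xmin)
  if (!length(sa_m2)) return(numeric())
  if (any(!is.finite(sa_m2)) || any(sa_m2 <= 0))
    stop_named("'sa_m2' must be positive and finite")
  ca <- alpha * sa_m2 / 1e4
  s <- sum(ca)
  if (s > basin_area_ha) ca <- ca * (basin_area_ha / s)
  ca
}

#' Nitrogen input and removal for a single water body
#'
#' `N_in = gamma * N_sur * CA` (kg yr-1; clamped at zero when the basin
#' surplus is negative) and `R_wet = N_in * rho / 100`.
#'
#' @param gamma delivery factor in \[0.3, 0.5\].
#' @param n_sur basin N surplus, kg ha-1 yr-1 (may be negative).
#' @param ca_ha contributing area, ha.
#' @param rho_percent removal efficiency, percent in (0, 100).
#' @return data.frame `n_in_kg_yr`, `r_wet_kg_yr` (vectorised).
#' @export
body_removal <- function(gamma, n_sur, ca_ha, rho_percent) {
  args <- list(gamma, n_sur, ca_ha, rho_percent)
  if (any(!vapply(args, function(a) all(is.finite(a)), logical(1))))
    stop_named("all inputs to body_removal() must be finite")
  n_in <- pmax(gamma * n_sur * ca_ha, 0)
  data.frame(n_in_kg_yr = n_in, r_wet_kg_yr = n_in * rho_percent / 100)
}

# Per-basin precomputation shared by the deterministic run, the Monte Carlo
# engine and the scenario evaluator. For each basin with at least one body:
# S_ha = sum of body areas (ha) and Wrho = sum of SA_ha * rho (percent), so
# that the basin removal under a draw (gamma, alpha) is
#   gamma * N_sur * alpha * scale * Wrho / 100,
# with scale = min(1, A_shd / (alpha * S_ha)) from the CA rescaling.
basin_terms <- function(bodies, basins, basin_n,
                        loss_ratios = default_loss_ratios()) {
  validate_table(bodies, "bodies", c("id", "area_m2", "basin3_id", "temp_c"))
  validate_table(basins, "basins",
                 c("basin3_id", "basin1_id", "area_ha", "f_paddy", "f_dryland",
                   "f_forest_grassland", "f_constructed"))
  validate_table(basin_n, "basin_nitrogen", c("basin3_id", "n_sur_kg_ha_yr"))
  i <- match(bodies$basin3_id, basins$basin3_id)
  if (anyNA(i))
    stop_named("body '%s' references unknown basin '%s'",
               bodies$id[which(is.na(i))[1]],
               bodies$basin3_id[which(is.na(i))[1]])
  j <- match(basins$basin3_id, basin_n$basin3_id)
  n_sur <- basin_n$n_sur_kg_ha_yr[j]
  has_bodies <- basins$basin3_id %in% bodies$basin3_id
  if (any(has_bodies & (is.na(n_sur))))
    stop_named("basin '%s' holds water bodies but has undefined N surplus",
               basins$basin3_id[which(has_bodies & is.na(n_sur))[1]])
  eff <- removal_efficiency(bodies$area_m2, bodies$temp_c)
  sa_ha <- bodies$area_m2 / 1e4
  S <- rowsum(sa_ha, bodies$basin3_id)
  Wr <- rowsum(sa_ha * eff$rho_percent, bodies$basin3_id)
  m <- match(basins$basin3_id, rownames(S))
  gam <- apply(basins[, c("f_paddy", "f_dryland", "f_forest_grassland",
                          "f_constructed")], 1L,
               function(fr) gamma_reduction(fr / sum(fr), loss_ratios))
  data.frame(basin3_id = basins$basin3_id, basin1_id = basins$basin1_id,
             area_ha = basins$area_ha,
             n_sur = pmax(ifelse(is.na(n_sur), 0, n_sur), 0),
             gamma_mean = gam,
             n_bodies = ifelse(is.na(m), 0L, tabulate(
               match(bodies$basin3_id, basins$basin3_id), nrow(basins))),
             S_ha = ifelse(is.na(m), 0, S[m, 1]),
             Wrho = ifelse(is.na(m), 0, Wr[m, 1]),
             stringsAsFactors = FALSE)
}

# Basin removal totals (kg yr-1) for per-basin parameter vectors.
basin_totals <- function(terms, gamma, alpha) {
  scale <- ifelse(terms$S_ha > 0,
                  pmin(1, terms$area_ha / (alpha * terms$S_ha)), 1)
  gamma * terms$n_sur * alpha * scale * terms$Wrho / 100
}

#' Deterministic per-body removal table
#'
#' Runs the whole removal chain at fixed parameters (basin-level delivery
#' factors from land use; a single watershed-area ratio `alpha`): removal
#' efficiency per body, contributing areas with basin rescaling, N input
#' and removal, and the areal removal rate per hectare of water surface.
#'
#' @param bodies one inventory snapshot.
#' @param basins basin table with land-use fractions and `area_ha`.
#' @param basin_n basin N surplus (`basin3_id`, `n_sur_kg_ha_yr`).
#' @param alpha watershed-to-water-body area ratio (default: geometric
#'   midpoint of \[3, 20\]).
#' @param loss_ratios loss ratios feeding [gamma_reduction()].
#' @return data.frame, one row per body: `id`, `basin3_id`, `basin1_id`,
#'   `area_m2`, `rho_percent`, `gamma`, `n_sur`, `ca_ha`, `n_in_kg_yr`,
#'   `r_wet_kg_yr`, `areal_rate_kg_ha_yr`.
#' @export
body_removal_table <- function(bodies, basins, basin_n,
                               alpha = sqrt(3 * 20),
                               loss_ratios = default_loss_ratios()) {
  check_number(alpha, "alpha", lower = 3, upper = 20)
  terms <- basin_terms(bodies, basins, basin_n, loss_ratios)
  eff <- removal_efficiency(bodies$area_m2, bodies$temp_c)
  i <- match(bodies$basin3_id, terms$basin3_id)
  # per-basin rescaling factor at this alpha
  scale <- ifelse(terms$S_ha > 0,
                  pmin(1, terms$area_ha / (alpha * terms$S_ha)), 1)
  ca <- alpha * (bodies$area_m2 / 1e4) * scale[i]
  rem <- body_removal(terms$gamma_mean[i], terms$n_sur[i], ca,
                      eff$rho_percent)
  data.frame(id = bodies$id, basin3_id = bodies$basin3_id,
             basin1_id = terms$basin1_id[i], area_m2 = bodies$area_m2,
             rho_percent = eff$rho_percent, gamma = terms$gamma_mean[i],
             n_sur = terms$n_sur[i], ca_ha = ca,
             n_in_kg_yr = rem$n_in_kg_yr, r_wet_kg_yr = rem$r_wet_kg_yr,
             areal_rate_kg_ha_yr = rem$r_wet_kg_yr / (bodies$area_m2 / 1e4),
             stringsAsFactors = FALSE)
}

#' Areal removal rates by size class
#'
#' Median and mean removal per hectare of water surface for small
#' (`area < threshold`) versus large bodies — the size dependence that
#' motivates small-body restoration.
#'
#' @param removal_table a [body_removal_table()] result.
#' @param threshold_m2 small-body threshold.
#' @return data.frame with one row per class: `class`, `n`,
#'   `median_kg_ha_yr`, `mean_kg_ha_yr`.
#' @export
class_areal_rates <- function(removal_table,
                              threshold_m2 = SMALL_BODY_THRESHOLD_M2) {
  validate_table(removal_table, "removal_table",
                 c("area_m2", "areal_rate_kg_ha_yr"))
  cls <- ifelse(removal_table$area_m2 < threshold_m2, "small", "large")
  out <- do.call(rbind, lapply(split(removal_table$areal_rate_kg_ha_yr, cls),
    function(x) data.frame(n = length(x), median_kg_ha_yr = stats::median(x),
                           mean_kg_ha_yr = mean(x))))
  data.frame(class = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Monte Carlo nitrogen-removal ensemble
#'
#' Propagates the uncertainty of the two most sensitive parameters through
#' the removal chain. Per draw and per third-order basin, the delivery
#' factor is drawn from a Normal centred on the basin's land-use value with
#' a 25% coefficient of variation, truncated to \[0.3, 0.5\] by resampling;
#' the watershed-area ratio is drawn from a lognormal (geometric
#' mean/standard deviation) truncated to \[3, 20\]. All bodies in a basin
#' share the basin's draw, which keeps the contributing-area rescaling
#' well defined. National totals are the per-draw sums over basins.
#'
#' @param bodies one inventory snapshot.
#' @param basins basin table.
#' @param basin_n basin N surplus table.
#' @param n_draws ensemble size (default 1000).
#' @param seed integer seed; fixed seed gives identical ensembles.
#' @param alpha_gmean,alpha_gsd geometric mean and geometric SD of the
#'   lognormal for alpha (defaults: midpoint of \[3, 20\] on the log scale,
#'   gsd 1.6).
#' @param alpha_range,gamma_range truncation ranges.
#' @param gamma_cv coefficient of variation for the delivery factor.
#' @param loss_ratios loss ratios feeding the basin delivery factors.
#' @return object of class `swb_mc_removal`: list with `per_basin`
#'   (basin3_id, n_bodies, area_ha, `m_wshd_median`, `m_wshd_q25`,
#'   `m_wshd_q75` in kg ha-1 yr-1), `national_draws_kg_yr`, and `national`
#'   (median/q25/q75 in kg yr-1 and kilotonnes yr-1; 1 kt = 1e6 kg).
#' @export
monte_carlo_removal <- function(bodies, basins, basin_n, n_draws = 1000L,
                                seed = 1L,
                                alpha_gmean = sqrt(3 * 20), alpha_gsd = 1.6,
                                alpha_range = c(3, 20),
                                gamma_range = c(0.3, 0.5), gamma_cv = 0.25,
                                loss_ratios = default_loss_ratios()) {
  check_number(n_draws, "n_draws", lower = 1)
  check_number(seed, "seed")
  check_number(alpha_gmean, "alpha_gmean", lower = alpha_range[1],
               upper = alpha_range[2])
  check_number(alpha_gsd, "alpha_gsd", lower = 1)
  check_number(gamma_cv, "gamma_cv", lower = 0, upper = 1)
  terms <- basin_terms(bodies, basins, basin_n, loss_ratios)
  nb <- nrow(terms)
  set.seed(as.integer(seed))
  totals <- matrix(0, nrow = nb, ncol = n_draws)
  for (dd in seq_len(n_draws)) {
    gam <- rnorm_trunc(nb, terms$gamma_mean, gamma_cv * terms$gamma_mean,
                       gamma_range[1], gamma_range[2])
    alp <- rlnorm_trunc(nb, log(alpha_gmean), log(alpha_gsd),
                        alpha_range[1], alpha_range[2])
    totals[, dd] <- basin_totals(terms, gam, alp)
  }
  m_wshd <- totals / terms$area_ha
  qs <- t(apply(m_wshd, 1L, stats::quantile, probs = c(0.25, 0.5, 0.75),
                names = FALSE))
  per_basin <- data.frame(basin3_id = terms$basin3_id,
                          basin1_id = terms$basin1_id,
                          n_bodies = terms$n_bodies, area_ha = terms$area_ha,
                          m_wshd_q25 = qs[, 1], m_wshd_median = qs[, 2],
                          m_wshd_q75 = qs[, 3], stringsAsFactors = FALSE)
  nat <- colSums(totals)
  natq <- stats::quantile(nat, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(
    per_basin = per_basin,
    national_draws_kg_yr = nat,
    national = list(median_kg_yr = natq[2], q25_kg_yr = natq[1],
                    q75_kg_yr = natq[3], median_kt_yr = natq[2] / 1e6,
                    iqr_kt_yr = (natq[3] - natq[1]) / 1e6),
    n_draws = as.integer(n_draws), seed = as.integer(seed)
  ), class = "swb_mc_removal")
}

#' @export
print.swb_mc_removal <- function(x, ...) {
  cat(sprintf("Monte Carlo N removal ensemble (%d draws)\n", x$n_draws))
  cat(sprintf("  national removal: median %.3g kt yr-1 (IQR %.3g kt yr-1)\n",
              x$national$median_kt_yr, x$national$iqr_kt_yr))
  cat(sprintf("  basins: %d; basin-scale median removal %.3g kg ha-1 yr-1\n",
              nrow(x$per_basin), stats::median(x$per_basin$m_wshd_median)))
  invisible(x)
}
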