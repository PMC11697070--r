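#' Value nitrogen removal against wastewater treatment
#'
#' Expresses the N removal service of water bodies as the cost of achieving
#' the same load reduction with wastewater treatment plants (WWTPs):
#' `E_w = R_awet / (C_in - C_out) * T_cost * 1000`, where `R_awet`
#' (kg yr-1) is the annual N removal, `C_in` and `C_out` (mg L-1) the mean
#' WWTP influent and effluent total-N concentrations, and `T_cost`
#' (CNY m-3) the treatment cost per cubic metre. The quotient
#' `R / (C_in - C_out)` is the wastewater volume (in 1000 m3) that removes
#' the same mass, hence the factor 1000. CNY converts to USD by a fixed
#' 2015 exchange rate with no inflation adjustment. The WWTP-equivalent
#' count is the removal divided by a typical plant's annual N removal,
#' rounded up (a fractional plant cannot be built).
#'
#' The concentration, cost and per-plant defaults are representative 2015
#' values for Chinese municipal WWTPs and are deliberately configurable.
#'
#' @param r_awet_kg_yr annual N removal, kg yr-1 (>= 0).
#' @param c_in,c_out influent / effluent TN, mg L-1 (`c_in > c_out > 0`).
#' @param t_cost treatment cost, CNY m-3 (> 0).
#' @param fx_rate CNY per USD (2015 average by default).
#' @param per_plant_removal_kg_yr annual N removal of one reference WWTP.
#' @return data.frame `treated_volume_m3_yr`, `e_w_cny`, `e_w_usd`,
#'   `wwtp_equivalents` (vectorised over `r_awet_kg_yr`).
#' @examples
#' valuation(1e6, c_in = 40, c_out = 20, t_cost = 2)
#' @export
valuation <- function(r_awet_kg_yr, c_in = 40, c_out = 15, t_cost = 1.3,
                      fx_rate = 6.23, per_plant_removal_kg_yr = 2.6e5) {
  if (any(!is.finite(r_awet_kg_yr)) || any(r_awet_kg_yr < 0))
    stop_named("'r_awet_kg_yr' must be finite and non-negative")
  check_number(c_in, "c_in", lower = .Machine$double.xmin)
  check_number(c_out, "c_out", lower = 0)
  if (c_in <= c_out)
    stop_named("non-positive concentration drop: c_in (%g) must exceed c_out (%g)",
               c_in, c_out)
  check_number(t_cost, "t_cost", lower = .Machine$double.xmin)
  check_number(fx_rate, "fx_rate", lower = .Machine$double.xmin)
  check_number(per_plant_removal_kg_yr, "per_plant_removal_kg_yr",
               lower = .Machine$double.xmin)
  vol <- r_awet_kg_yr / (c_in - c_out) * 1000   # m3 yr-1
  e_cny <- vol * t_cost
  data.frame(treated_volume_m3_yr = vol, e_w_cny = e_cny,
             e_w_usd = e_cny / fx_rate,
             wwtp_equivalents = ceiling(r_awet_kg_yr / per_plant_removal_kg_yr))
}
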