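#' Fit the size-frequency power law to large-body bins
#'
#' Undisturbed landscapes show a power-law ("fractal") relation
#' `N_w = c A^d` between water-body surface area and abundance. Preferential
#' loss of small bodies bends the observed distribution below a breakpoint,
#' so the law is fitted only to bins entirely at or above the threshold and
#' later extrapolated below it to quantify the deficit. The fit is an
#' unweighted least-squares line on (log10 representative area, log10
#' count); bins above the threshold with zero count are excluded with a
#' warning.
#'
#' @param dist a [bin_inventory()] result.
#' @param threshold_m2 breakpoint area in m2 (default `10^4.5`).
#' @param min_abs_d fits with `|d|` below this are flagged non-fractal
#'   (default 0.05).
#' @return object of class `swb_powerlaw_fit`: list with `c`, `d`,
#'   `r_squared`, `p_value` (slope test), `n_bins_used`, `threshold_m2`,
#'   `fractal` flag.
#' @examples
#' b <- data.frame(id = as.character(1:6), area_m2 = 10^c(5.2, 5.2, 5.7, 6.2, 6.2, 6.7))
#' # exact two-per-bin data gives d = 0 (flagged non-fractal)
#' fit <- suppressWarnings(fit_power_law(bin_inventory(b), threshold_m2 = 1e5))
#' @export
fit_power_law <- function(dist, threshold_m2 = SMALL_BODY_THRESHOLD_M2,
                          min_abs_d = 0.05) {
  if (!inherits(dist, "swb_size_dist"))
    stop_named("'dist' must be a swb_size_dist from bin_inventory()")
  check_number(threshold_m2, "threshold_m2", lower = .Machine$double.xmin)
  above <- dist$lo_m2 >= threshold_m2 * (1 - 1e-12)
  use <- above & dist$count > 0
  if (any(above & dist$count == 0))
    warning(sprintf("%d zero-count bin(s) above threshold excluded from fit",
                    sum(above & dist$count == 0)), call. = FALSE)
  if (sum(use) < 3L)
    stop_named("insufficient bins: need >= 3 non-zero bins above threshold, have %d",
               sum(use))
  x <- log10(dist$rep_area_m2[use])
  y <- log10(dist$count[use])
  fit <- stats::lm(y ~ x)
  # exact log-linear input triggers lm's perfect-fit warning; harmless here
  sm <- suppressWarnings(summary(fit))
  d <- unname(stats::coef(fit)[2])
  structure(list(
    c = 10^unname(stats::coef(fit)[1]),
    d = d,
    r_squared = sm$r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    n_bins_used = sum(use),
    threshold_m2 = threshold_m2,
    fractal = abs(d) >= min_abs_d,
    se_intercept = unname(sm$coefficients[1, 2]),
    se_d = unname(sm$coefficients[2, 2]),
    x_bar = mean(x), ssx = sum((x - mean(x))^2), sigma = sm$sigma,
    df_resid = fit$df.residual
  ), class = "swb_powerlaw_fit")
}

#' @export
print.swb_powerlaw_fit <- function(x, ...) {
  cat(sprintf("Size-frequency power law: N_w = %.4g * A^%.4g\n", x$c, x$d))
  cat(sprintf("  fitted on %d bins >= %.3g m2; R2 = %.4f, p = %.3g%s\n",
              x$n_bins_used, x$threshold_m2, x$r_squared, x$p_value,
              if (x$fractal) "" else "  [non-fractal: |d| below minimum]"))
  invisible(x)
}

#' Predicted bin count under a fitted power law
#'
#' @param fit a `swb_powerlaw_fit`.
#' @param area_m2 representative area(s).
#' @return expected count(s) `c * A^d`.
#' @export
expected_count <- function(fit, area_m2) {
  if (!inherits(fit, "swb_powerlaw_fit")) stop_named("'fit' must be a swb_powerlaw_fit")
  fit$c * area_m2^fit$d
}

#' Fractal deficit of small water bodies
#'
#' Extrapolates the fitted power law into the sub-threshold bins and takes
#' the per-bin shortfall `max(expected - observed, 0)`. The deficit counts,
#' converted to area at the bin's geometric midpoint, define the
#' restoration area that would recover the theoretical fractal size
#' distribution.
#'
#' @param dist a [bin_inventory()] result covering sub-threshold bins.
#' @param fit the [fit_power_law()] result for the same landscape.
#' @return object of class `swb_fractal_deficit`: data.frame with one row
#'   per sub-threshold bin (`log10_lo`, `log10_hi`, `rep_area_m2`,
#'   `expected_count`, `observed_count`, `deficit_count`,
#'   `deficit_area_m2`) with attributes `total_deficit_area_m2` and
#'   `threshold_m2`.
#' @export
fractal_deficit <- function(dist, fit) {
  if (!inherits(dist, "swb_size_dist"))
    stop_named("'dist' must be a swb_size_dist")
  if (!inherits(fit, "swb_powerlaw_fit"))
    stop_named("'fit' must be a swb_powerlaw_fit")
  thr <- round(log10(fit$threshold_m2), 9)
  if (!any(abs(c(dist$log10_lo, dist$log10_hi) - thr) < 1e-9))
    stop_named("fit threshold 10^%g m2 is not a bin edge of 'dist'", thr)
  below <- dist$log10_hi <= thr + 1e-9
  if (!any(below))
    stop_named("'dist' has no bins below the threshold")
  sub <- dist[below, , drop = FALSE]
  exp_n <- expected_count(fit, sub$rep_area_m2)
  out <- data.frame(
    log10_lo = sub$log10_lo, log10_hi = sub$log10_hi,
    rep_area_m2 = sub$rep_area_m2,
    expected_count = exp_n,
    observed_count = sub$count,
    deficit_count = pmax(exp_n - sub$count, 0)
  )
  out$deficit_area_m2 <- out$deficit_count * out$rep_area_m2
  structure(out, class = c("swb_fractal_deficit", "data.frame"),
            total_deficit_area_m2 = sum(out$deficit_area_m2),
            threshold_m2 = fit$threshold_m2)
}

#' @export
print.swb_fractal_deficit <- function(x, ...) {
  cat(sprintf("Fractal deficit below %.3g m2: %.0f bodies, %.4g ha to restore\n",
              attr(x, "threshold_m2"), sum(x$deficit_count),
              attr(x, "total_deficit_area_m2") / 1e4))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot a size distribution with its fitted power law
#'
#' Log-log size-frequency plot; observed bin counts as points, the fitted
#' law as a dashed line, the small-body threshold as a vertical line.
#'
#' @param x a `swb_size_dist`.
#' @param fit optional `swb_powerlaw_fit` to overlay.
#' @param threshold_m2 threshold marker (default `10^4.5`).
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.swb_size_dist <- function(x, fit = NULL,
                               threshold_m2 = SMALL_BODY_THRESHOLD_M2, ...) {
  keep <- x$count > 0
  plot(x$rep_area_m2[keep], x$count[keep], log = "xy",
       xlab = "surface area (m2)", ylab = "number of water bodies",
       pch = 19, ...)
  graphics::abline(v = threshold_m2, lty = 3, col = "grey40")
  if (!is.null(fit)) {
    a <- range(x$rep_area_m2)
    aa <- 10^seq(log10(a[1]), log10(a[2]), length.out = 100)
    graphics::lines(aa, expected_count(fit, aa), lty = 2, col = "firebrick")
  }
  invisible(x)
}
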