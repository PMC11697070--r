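# Independent single-expression oracles, coded separately from the package
# pipeline. Each recomputes a quantity from first principles so agreement
# is evidence, not tautology.

# Residence time, rate constant and removal efficiency as one expression
# each, straight from the first-order kinetics model.
oracle_tau <- function(sa) 1.66 * sa^0.24
oracle_k <- function(sa, temp) {
  exp(-1.07 * log(1.66 * sa^0.24) + 0.29 * (temp - 20) / 10 - 0.5)
}
oracle_rho <- function(sa, temp) {
  (1 - exp(-exp(-1.07 * log(1.66 * sa^0.24) + 0.29 * (temp - 20) / 10 - 0.5) *
             (1.66 * sa^0.24))) * 100
}

# Closed-form unweighted least squares on (log10 area, log10 count),
# avoiding lm() so the fit has an independent reference.
oracle_loglog_fit <- function(area_mid, counts) {
  x <- log10(area_mid); y <- log10(counts)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  list(c = 10^intercept, d = slope)
}

# Continuous Pareto maximum-likelihood exponent (Clauset-style) for
# cross-checking the sign and order of the binned-fit exponent: for a
# density ~ x^-(alpha+1), the binned half-decade counts scale as x^-alpha,
# so the size-frequency exponent is d ~ -alpha = 1 - alpha_mle_pdf with
# alpha_mle_pdf = 1 + n / sum(log(x / xmin)).
oracle_pareto_mle_d <- function(x, xmin) {
  x <- x[x >= xmin]
  1 - (1 + length(x) / sum(log(x / xmin)))
}

# Build a size-distribution object directly from bin edges and counts,
# bypassing bin_inventory(), for fit unit tests on exact inputs.
make_dist <- function(edges_log10, counts, area_m2 = NULL) {
  lo <- edges_log10[-length(edges_log10)]
  hi <- edges_log10[-1]
  rep_a <- 10^((lo + hi) / 2)
  if (is.null(area_m2)) area_m2 <- counts * rep_a
  structure(
    data.frame(log10_lo = lo, log10_hi = hi, lo_m2 = 10^lo, hi_m2 = 10^hi,
               rep_area_m2 = rep_a, count = counts, area_m2 = area_m2),
    class = c("swb_size_dist", "data.frame"),
    n_bodies = sum(counts), bin_width = diff(edges_log10)[1])
}
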