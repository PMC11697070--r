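#' @keywords internal
"_PACKAGE"

# Area below which a lentic body counts as "small" (m2), per the Chinese
# national standard for small wetlands.
SMALL_BODY_THRESHOLD_M2 <- 10^4.5

# Seven-category land-cover vocabulary used for loss-pathway accounting.
DESTINATION_CLASSES <- c("cropland", "forest", "grassland", "constructed",
                         "water", "saline-alkali", "other")

# Land-use classes entering the catchment delivery factor.
GAMMA_LANDUSE_CLASSES <- c("paddy", "dryland", "forest_grassland", "constructed")

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && !is.finite(x)))
    stop_named("'%s' must be a single finite number", name)
  if (is.finite(x) && (x < lower || x > upper))
    stop_named("'%s' = %g is outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] >= x[2])
    stop_named("'%s' must be a finite [min, max] pair with min < max", name)
  invisible(x)
}

#' Validate that a table carries the expected columns
#'
#' Schema guard used at every pipeline stage boundary: failures name the
#' offending table and column so a broken CSV is traceable.
#'
#' @param df data.frame to check.
#' @param table human-readable table name (e.g. a file name).
#' @param cols required column names.
#' @return `df`, invisibly.
#' @export
validate_table <- function(df, table, cols) {
  if (!is.data.frame(df))
    stop_named("'%s' is not a data.frame", table)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_named("table '%s' is missing column(s): %s", table,
               paste(missing, collapse = ", "))
  invisible(df)
}

# Derive a reproducible per-stage substream seed from the root seed.
# Kept below 2^31 - 1 so it is always a valid R integer.
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 7919 * k) %% 2147483647)
}

# Truncated normal via resampling (no boundary atoms, unlike clipping).
rnorm_trunc <- function(n, mean, sd, lower, upper, max_iter = 1000L) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(max_iter)) {
    bad <- which(x < lower | x > upper)
    if (!length(bad)) return(x)
    x[bad] <- stats::rnorm(length(bad), if (length(mean) > 1L) mean[bad] else mean,
                           if (length(sd) > 1L) sd[bad] else sd)
  }
  stop_named("truncated-normal sampling failed to converge; check mean/sd against [%g, %g]",
             lower, upper)
}

# Truncated lognormal via resampling.
rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper, max_iter = 1000L) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (i in seq_len(max_iter)) {
    bad <- which(x < lower | x > upper)
    if (!length(bad)) return(x)
    x[bad] <- stats::rlnorm(length(bad), meanlog, sdlog)
  }
  stop_named("truncated-lognormal sampling failed to converge")
}

# Tiny FNV-1a hash of a string; stamps outputs with the resolved config.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
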