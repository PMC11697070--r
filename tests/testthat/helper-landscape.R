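# Small desk-scale landscape configurations used across test files.

tiny_config <- function(seed = 1L, n_bodies = 3000, d = -0.8,
                        area_range = c(10^2.5, 10^7), ...) {
  landscape_config(
    n_basins_first = 2L, n_basins_third_per_first = 3L,
    powerlaw_c = powerlaw_c_for_total(n_bodies, d, area_range),
    powerlaw_d = d, area_range_m2 = area_range, seed = seed, ...)
}

# A uniform-surplus nitrogen table for a landscape's basins.
uniform_basin_n <- function(basins, n_sur = 50) {
  data.frame(basin3_id = basins$basin3_id, n_sur_kg_ha_yr = n_sur,
             stringsAsFactors = FALSE)
}
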