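budget_row <- function(unit = "U1", year = 2015, fert = 0, man = 0, dep = 0,
                       bnf = 0, str = 0, crop = 0) {
  data.frame(unit_id = unit, year = year, fert = fert, man = man, dep = dep,
             bnf = bnf, str = str, crop = crop, stringsAsFactors = FALSE)
}

test_that("the soil-surface budget is exact component arithmetic", {
  expect_equal(compute_surplus(budget_row())$ns, 0)
  b <- compute_surplus(budget_row(fert = 100, man = 20, dep = 10, bnf = 5,
                                  str = 5, crop = 90))
  expect_equal(b$ns, 50)
  # a net sink is flagged, not rejected
  expect_warning(neg <- compute_surplus(budget_row(fert = 10, crop = 90)),
                 "negative")
  expect_equal(neg$ns, -80)
  # missing component names the component and the unit
  bad <- budget_row(unit = "U9"); bad$dep <- NA_real_
  expect_error(compute_surplus(bad), "dep.*U9")
})

test_that("surplus is linear in each component with unit coefficient", {
  base <- compute_surplus(budget_row(fert = 50, man = 5, dep = 5, bnf = 5,
                                     str = 5, crop = 40))$ns
  for (nm in c("fert", "man", "dep", "bnf", "str")) {
    args <- list(fert = 50, man = 5, dep = 5, bnf = 5, str = 5, crop = 40)
    args[[nm]] <- args[[nm]] + 7
    expect_equal(compute_surplus(do.call(budget_row, args))$ns, base + 7)
  }
})

test_that("three-year averaging centres each component", {
  mk <- function(years, ferts) do.call(rbind, Map(function(y, f)
    budget_row(year = y, fert = f, crop = 1), years, ferts))
  # constant years: unchanged
  avg <- suppressWarnings(three_year_average(mk(2014:2016, c(80, 80, 80)), 2015))
  expect_equal(avg$fert, 80)
  # linear trend: centre value
  avg2 <- suppressWarnings(three_year_average(mk(2014:2016, c(70, 80, 90)), 2015))
  expect_equal(avg2$fert, 80)
  # random triple vs direct arithmetic mean
  set.seed(4)
  f <- runif(3, 0, 200)
  avg3 <- suppressWarnings(three_year_average(mk(2014:2016, f), 2015))
  expect_equal(avg3$fert, mean(f))
  expect_equal(avg3$ns, mean(f) - 1)
  expect_error(three_year_average(mk(2014:2015, c(1, 2)), 2015), "missing")
})

mk_cells <- function(n_crop, n_non, unit = "U1", area = 10) {
  n <- n_crop + n_non
  data.frame(cell_id = sprintf("c%02d", seq_len(n)), unit_id = unit,
             basin3_id = "B1", land_class = rep(c("cropland", "non-cropland"),
                                                c(n_crop, n_non)),
             cell_area_ha = area, stringsAsFactors = FALSE)
}

test_that("downscaling routes agricultural surplus to cropland, deposition elsewhere", {
  bud <- compute_surplus(budget_row(fert = 100, man = 20, dep = 30, bnf = 5,
                                    str = 5, crop = 90))
  cells <- mk_cells(1, 1)
  cs <- downscale_surplus(bud, cells)
  # unit mass: ag = (130 - 90) * 20 ha = 800 kg; dep = 30 * 20 = 600 kg
  expect_equal(cs$ns_kg[cs$land_class == "cropland"], 800)
  expect_equal(cs$ns_kg[cs$land_class == "non-cropland"], 600)
  # same unit split into twice as many half-size cells: per-cell mass
  # halves, the per-hectare rate is unchanged, total mass is conserved
  cs2 <- downscale_surplus(bud, mk_cells(2, 2, area = 5))
  expect_equal(sum(cs2$ns_kg), sum(cs$ns_kg))
  expect_equal(unique(cs2$ns_kg_ha[cs2$land_class == "cropland"]),
               unique(cs$ns_kg_ha[cs$land_class == "cropland"]))
  expect_equal(unique(cs2$ns_kg[cs2$land_class == "cropland"]),
               cs$ns_kg[cs$land_class == "cropland"] / 2)
})

test_that("downscaling conserves mass and is permutation invariant", {
  set.seed(11)
  bud <- suppressWarnings(compute_surplus(do.call(rbind, lapply(1:4, function(i)
    budget_row(unit = paste0("U", i), fert = runif(1, 0, 200),
               man = runif(1, 0, 50), dep = runif(1, 0, 40),
               bnf = runif(1, 0, 20), str = runif(1, 0, 30),
               crop = runif(1, 0, 150))))))
  cells <- do.call(rbind, lapply(1:4, function(i) {
    cc <- mk_cells(sample(1:5, 1), sample(1:5, 1), unit = paste0("U", i),
                   area = runif(1, 5, 20))
    cc$basin3_id <- paste0("B", sample(1:2, nrow(cc), TRUE))
    cc$cell_id <- paste0(cc$cell_id, "_", i)
    cc
  }))
  cs <- downscale_surplus(bud, cells)
  area_u <- rowsum(cells$cell_area_ha, cells$unit_id)[bud$unit_id, 1]
  expect_equal(rowsum(cs$ns_kg, cs$unit_id)[bud$unit_id, 1],
               bud$ns * area_u, tolerance = 1e-6)
  perm <- cells[sample(nrow(cells)), ]
  csp <- downscale_surplus(bud, perm)
  expect_equal(csp$ns_kg[match(cs$cell_id, csp$cell_id)], cs$ns_kg,
               tolerance = 1e-12)
  # basin aggregation conserves the same mass
  bs <- basin_surplus(cs)
  expect_equal(sum(bs$ns_kg), sum(bud$ns * area_u), tolerance = 1e-6)
})

test_that("impossible and degenerate allocations are handled explicitly", {
  bud <- compute_surplus(budget_row(fert = 100, dep = 10, crop = 50))
  expect_error(downscale_surplus(bud, mk_cells(0, 2)), "cropland")
  expect_warning(cs <- downscale_surplus(bud, mk_cells(2, 0)),
                 "deposition")
  expect_equal(sum(cs$ns_kg), bud$ns * 20)   # dep folded into cropland
  # weighted two-cell basin mean, by hand
  cells <- mk_cells(1, 1); cells$cell_area_ha <- c(30, 10)
  cs2 <- downscale_surplus(bud, cells)
  bs <- basin_surplus(cs2)
  expect_equal(bs$n_sur_kg_ha_yr, sum(cs2$ns_kg) / 40)
  # a basin without cells is flagged undefined
  expect_warning(bs2 <- basin_surplus(cs2, basins = data.frame(
    basin3_id = c("B1", "B9"))), "no grid cells")
  expect_true(bs2$undefined[bs2$basin3_id == "B9"])
})
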