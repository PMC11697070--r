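# Build a controlled two-epoch basin history: one small body per basin
# whose area moves by `swb_change` percent, with prescribed surplus levels.
toy_landscape <- function(ns_first, ns_last, swb_change_pct) {
  nb <- length(ns_first)
  ids <- sprintf("T%02d", seq_len(nb))
  bn <- rbind(
    data.frame(basin3_id = ids, year = 1995, n_sur_kg_ha_yr = ns_first),
    data.frame(basin3_id = ids, year = 2015, n_sur_kg_ha_yr = ns_last))
  a0 <- 1000
  bodies <- rbind(
    data.frame(id = paste0("w", ids), year = 1995, area_m2 = a0,
               basin3_id = ids, stringsAsFactors = FALSE),
    data.frame(id = paste0("w", ids), year = 2015,
               area_m2 = a0 * (1 + swb_change_pct / 100),
               basin3_id = ids, stringsAsFactors = FALSE))
  list(basin_n = bn, bodies = bodies)
}

test_that("risk quadrants follow their definitions", {
  # NS = 20 rising with SWB loss: current and future high (the hatched class)
  tl <- toy_landscape(15, 20, -10)
  r <- classify_risk(tl$basin_n, tl$bodies)
  expect_identical(r$risk_class, "both")
  # NS = 10 rising with SWB loss: future risk only
  tl2 <- toy_landscape(8, 10, -10)
  expect_identical(classify_risk(tl2$basin_n, tl2$bodies)$risk_class, "future")
  # zero change is not-at-risk (strict inequalities)
  tl3 <- toy_landscape(20, 20, 0)
  expect_identical(classify_risk(tl3$basin_n, tl3$bodies)$risk_class, "low")
})

test_that("an eight-basin table matches exhaustive enumeration", {
  ns_first <- c(10, 10, 25, 25, 10, 25, 10, 25)
  ns_last <- c(12, 8, 30, 20, 12, 30, 8, 18)
  swb <- c(-20, -20, -20, -20, 15, 15, 15, -5)
  tl <- toy_landscape(ns_first, ns_last, swb)
  r <- classify_risk(tl$basin_n, tl$bodies, ns_threshold = 17)
  # brute-force oracle: enumerate the definitions row by row
  cur <- ns_last > 17 & swb < 0
  fut <- ns_last > ns_first & swb < 0
  expect_identical(r$current_high, cur)
  expect_identical(r$future_high, fut)
  expect_identical(unname(risk_counts(r)[c("both", "current", "future", "low")]),
                   c(sum(cur & fut), sum(cur & !fut), sum(fut & !cur),
                     sum(!cur & !fut)))
  # threshold monotonicity: raising the bar never adds current-risk basins
  n_cur <- vapply(c(5, 17, 25, 40), function(th)
    sum(classify_risk(tl$basin_n, tl$bodies, ns_threshold = th)$current_high),
    integer(1))
  expect_true(all(diff(n_cur) <= 0))
})

test_that("basins with missing epochs are flagged unclassifiable", {
  tl <- toy_landscape(c(10, 20), c(12, 25), c(-10, -10))
  bn <- tl$basin_n[!(tl$basin_n$basin3_id == "T01" & tl$basin_n$year == 1995), ]
  r <- classify_risk(bn, tl$bodies)
  expect_true(r$unclassifiable[r$basin3_id == "T01"])
  expect_identical(r$risk_class[r$basin3_id == "T02"], "both")
})

test_that("scenario construction honours the equal-area contract exactly", {
  edges <- seq(2.5, 7, 0.5)
  mids <- 10^((edges[-10] + edges[-1]) / 2)
  counts <- 1e6 * mids^-0.8
  fit <- fit_power_law(make_dist(edges, counts), threshold_m2 = 10^4.5)
  # deficit of exactly 2 bodies in one bin of representative area a
  obs <- counts; obs[3] <- obs[3] - 2
  def <- fractal_deficit(make_dist(edges, obs), fit)
  sp <- build_scenarios(def, "B01")
  a <- mids[3]
  expect_equal(sp$body_area_m2[sp$scenario == "S1"], c(a, a))
  expect_equal(sp$body_area_m2[sp$scenario == "S2"], rep(2 * a / 10, 10))
  expect_equal(sp$body_area_m2[sp$scenario == "S3"], 2 * a)
  for (s in c("S1", "S2", "S3"))
    expect_equal(sum(sp$body_area_m2[sp$scenario == s]),
                 attr(sp, "total_restore_area_m2"), tolerance = 1e-9)
  # all S1 bodies sit below the small-body threshold
  expect_true(all(sp$body_area_m2[sp$scenario == "S1"] < 10^4.5))
  # zero deficit: empty specification, reported not failed
  expect_message(sp0 <- build_scenarios(fractal_deficit(
    make_dist(edges, counts * 2), fit), "B02"), "zero")
  expect_identical(nrow(sp0), 0L)
})

test_that("S1 sizes reproduce the per-bin deficit exactly on a synthetic basin", {
  ls <- generate_landscape(tiny_config(seed = 61, n_bodies = 20000,
                                       small_loss_fraction_per_decade = 0.35))
  cur <- snapshot(ls, 2015)
  b1 <- cur[cur$basin1_id == "B01", ]
  edges <- seq(2.5, 7, 0.5)
  dist <- bin_inventory(b1, edges = edges)
  def <- fractal_deficit(dist, fit_power_law(dist))
  sp <- build_scenarios(def, "B01")
  s1 <- sp$body_area_m2[sp$scenario == "S1"]
  got <- table(factor(signif(s1, 10),
                      levels = signif(def$rep_area_m2, 10)))
  expect_equal(as.integer(got), as.integer(round(def$deficit_count)))
})

test_that("scenario evaluation is deterministic and null on zero restoration", {
  ls <- generate_landscape(tiny_config(seed = 67, n_bodies = 3000,
                                       small_loss_fraction_per_decade = 0.3))
  cur <- snapshot(ls, 2015)
  bn <- uniform_basin_n(ls$basins, 40)
  edges <- seq(2.5, 7, 0.5)
  dist <- bin_inventory(cur, edges = edges)
  fit <- fit_power_law(dist)
  empty <- structure(
    data.frame(scenario = character(), basin1_id = character(),
               body_area_m2 = numeric()),
    class = c("swb_scenarios", "data.frame"), total_restore_area_m2 = 0)
  r0 <- evaluate_scenarios(empty, cur, ls$basins, bn, n_draws = 5, seed = 1)
  expect_equal(r0$summary$median_increase_pct, c(0, 0, 0))
  # determinism under a fixed seed
  def <- fractal_deficit(dist, fit)
  sp <- build_scenarios(def, "B01")
  r1 <- evaluate_scenarios(sp, cur, ls$basins, bn, n_draws = 30, seed = 5)
  r2 <- evaluate_scenarios(sp, cur, ls$basins, bn, n_draws = 30, seed = 5)
  expect_identical(r1$draws_pct, r2$draws_pct)
  expect_identical(r1$summary, r2$summary)
})

test_that("median gains order S1 > S2 > S3 under uniform surplus", {
  ls <- generate_landscape(tiny_config(seed = 71, n_bodies = 6000,
                                       small_loss_fraction_per_decade = 0.35))
  cur <- snapshot(ls, 2015)
  bn <- uniform_basin_n(ls$basins, 50)
  edges <- seq(2.5, 7, 0.5)
  specs <- combine_scenarios(lapply(unique(cur$basin1_id), function(b1) {
    d <- bin_inventory(cur[cur$basin1_id == b1, ], edges = edges)
    suppressWarnings(build_scenarios(fractal_deficit(d, fit_power_law(d)), b1))
  }))
  res <- evaluate_scenarios(specs, cur, ls$basins, bn, n_draws = 120,
                            seed = 3)
  m <- res$summary$median_increase_pct
  expect_gt(m[1], m[2]); expect_gt(m[2], m[3])
  expect_true(all(res$draws_pct >= 0))
  # oracle: with uniform surplus the gain at fixed parameters is driven by
  # sum(SA * rho(SA)); the smaller the restored bodies, the larger the sum
  temp <- mean(ls$basins$temp_c)
  gain <- vapply(c("S1", "S2", "S3"), function(s) {
    a <- specs$body_area_m2[specs$scenario == s]
    sum(a / 1e4 * oracle_rho(a, temp))
  }, numeric(1))
  expect_true(gain[1] > gain[2] && gain[2] > gain[3])
})
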