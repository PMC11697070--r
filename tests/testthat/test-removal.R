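test_that("efficiency chain matches the independent single-expression oracle", {
  # centring identity of the temperature factor
  expect_equal(removal_efficiency(1000, 20)$t_c, 0)
  # the worked half-decade threshold case
  eff <- removal_efficiency(10^4.5, 20)
  expect_equal(eff$tau_days, oracle_tau(10^4.5), tolerance = 1e-12)
  expect_equal(eff$tau_days, 19.96, tolerance = 1e-3)
  expect_equal(eff$rho_percent, oracle_rho(10^4.5, 20), tolerance = 1e-12)
  expect_equal(eff$rho_percent, 38.8, tolerance = 2e-3)
  # random sweep against the oracle, relative 1e-9
  set.seed(2)
  sa <- 10^runif(300, 2.5, 7); tc <- runif(300, -5, 30)
  eff2 <- removal_efficiency(sa, tc)
  expect_equal(eff2$tau_days, oracle_tau(sa), tolerance = 1e-9)
  expect_equal(eff2$k_per_day, oracle_k(sa, tc), tolerance = 1e-9)
  expect_equal(eff2$rho_percent, oracle_rho(sa, tc), tolerance = 1e-9)
  expect_error(removal_efficiency(0, 20), "sa_m2")
})

test_that("efficiency is monotone: smaller and warmer bodies remove more", {
  expect_gt(removal_efficiency(10^3, 20)$rho_percent,
            removal_efficiency(10^4.5, 20)$rho_percent)
  sa <- 10^seq(2.5, 7, length.out = 50)
  rho_sa <- removal_efficiency(sa, 15)$rho_percent
  expect_true(all(diff(rho_sa) < 0))
  temps <- seq(-5, 30, length.out = 50)
  rho_t <- removal_efficiency(10^4, temps)$rho_percent
  expect_true(all(diff(rho_t) > 0))
})

test_that("the delivery factor hits its analytic bounds exactly", {
  expect_identical(gamma_reduction(c(1, 0, 0, 0), c(0, 0, 0, 0)), 0.3)
  expect_identical(gamma_reduction(c(1, 0, 0, 0), c(1, 1, 1, 1)), 0.5)
  expect_equal(gamma_reduction(c(0.5, 0.5, 0, 0), c(0.4, 0.2, 0, 0)), 0.36)
  expect_error(gamma_reduction(c(0.5, 0.4, 0, 0), rep(0.1, 4)), "sum to 1")
  expect_error(gamma_reduction(c(1, 0, 0, 0), c(2, 0, 0, 0)), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:50) {
    f <- as.vector(rmultinom(1, 100, runif(4))) / 100
    g <- gamma_reduction(f, runif(4))
    expect_gte(g, 0.3); expect_lte(g, 0.5)
  }
})

test_that("contributing areas rescale so basins are never overdrawn", {
  # single body below capacity: unscaled alpha * SA (in ha)
  expect_equal(contributing_areas(1e4, 5, 1000), 5)
  # two equal bodies overdrawing a basin by 2x: each halved, sum = basin
  ca <- contributing_areas(c(1e6, 1e6), 10, 1000)
  expect_equal(sum(ca), 1000)
  expect_equal(ca[1], ca[2])
  expect_equal(ca[1], 500)
  # property: the sum never exceeds the basin area
  set.seed(5)
  for (i in 1:25) {
    sa <- 10^runif(sample(1:50, 1), 3, 7)
    basin <- runif(1, 10, 1e5)
    expect_lte(sum(contributing_areas(sa, runif(1, 3, 20), basin)),
               basin + 1e-9)
  }
  expect_error(contributing_areas(1e4, 2.5, 1000), "alpha")
  expect_identical(contributing_areas(numeric(), 5, 1000), numeric())
})

test_that("body-level input and removal are exact arithmetic with clamping", {
  expect_equal(body_removal(0.4, 0, 10, 40)$r_wet_kg_yr, 0)
  r <- body_removal(0.4, 50, 10, 40)
  expect_equal(r$n_in_kg_yr, 200)
  expect_equal(r$r_wet_kg_yr, 80)
  # negative basin surplus clamps the input at zero
  expect_equal(body_removal(0.4, -30, 10, 40)$n_in_kg_yr, 0)
})

test_that("the pipeline removal table equals a brute-force per-body recomputation", {
  ls <- generate_landscape(tiny_config(seed = 41, n_bodies = 4000))
  bodies <- snapshot(ls, 2015)
  bn <- uniform_basin_n(ls$basins, 60)
  alpha <- 8
  tab <- body_removal_table(bodies, ls$basins, bn, alpha = alpha)
  lr <- default_loss_ratios()
  # oracle: recompute each body independently, including the rescaling
  for (b3 in unique(bodies$basin3_id)) {
    rows <- bodies[bodies$basin3_id == b3, ]
    bas <- ls$basins[ls$basins$basin3_id == b3, ]
    gam <- gamma_reduction(unlist(bas[c("f_paddy", "f_dryland",
                                        "f_forest_grassland",
                                        "f_constructed")]), lr)
    ca <- contributing_areas(rows$area_m2, alpha, bas$area_ha)
    rho <- oracle_rho(rows$area_m2, rows$temp_c)
    rwet <- pmax(gam * 60 * ca, 0) * rho / 100
    got <- tab$r_wet_kg_yr[match(rows$id, tab$id)]
    expect_equal(got, rwet, tolerance = 1e-9)
  }
  # basin-level mass constraint: sum N_in <= gamma * N_sur * A_shd,
  # with equality when the contributing-area rescaling triggered
  nin <- rowsum(tab$n_in_kg_yr, tab$basin3_id)
  for (b3 in rownames(nin)) {
    bas <- ls$basins[ls$basins$basin3_id == b3, ]
    gam <- tab$gamma[match(b3, tab$basin3_id)]
    cap <- gam * 60 * bas$area_ha
    expect_lte(unname(nin[b3, 1]), cap * (1 + 1e-9))
    naive <- alpha * sum(tab$area_m2[tab$basin3_id == b3]) / 1e4
    if (naive > bas$area_ha)
      expect_equal(unname(nin[b3, 1]), cap, tolerance = 1e-9)
  }
})

test_that("degenerate Monte Carlo collapses to the deterministic run", {
  ls <- generate_landscape(tiny_config(seed = 43, n_bodies = 2000))
  bodies <- snapshot(ls, 2015)
  bn <- uniform_basin_n(ls$basins, 45)
  mc <- monte_carlo_removal(bodies, ls$basins, bn, n_draws = 1, seed = 99,
                            alpha_gmean = 8, alpha_gsd = 1, gamma_cv = 0)
  det <- body_removal_table(bodies, ls$basins, bn, alpha = 8)
  expect_equal(unname(mc$national$median_kg_yr), sum(det$r_wet_kg_yr),
               tolerance = 1e-9)
})

test_that("ensembles are reproducible under a fixed seed", {
  ls <- generate_landscape(tiny_config(seed = 47, n_bodies = 2000))
  bodies <- snapshot(ls, 2015)
  bn <- uniform_basin_n(ls$basins)
  a <- monte_carlo_removal(bodies, ls$basins, bn, n_draws = 50, seed = 7)
  b <- monte_carlo_removal(bodies, ls$basins, bn, n_draws = 50, seed = 7)
  expect_identical(a$national_draws_kg_yr, b$national_draws_kg_yr)
  expect_identical(a$per_basin, b$per_basin)
  c <- monte_carlo_removal(bodies, ls$basins, bn, n_draws = 50, seed = 8)
  expect_false(identical(a$national_draws_kg_yr, c$national_draws_kg_yr))
})

test_that("small bodies out-remove large ones per hectare of water", {
  for (seed in c(53, 59)) {
    ls <- generate_landscape(tiny_config(seed = seed, n_bodies = 4000))
    bodies <- snapshot(ls, 2015)
    tab <- body_removal_table(bodies, ls$basins, uniform_basin_n(ls$basins))
    rates <- class_areal_rates(tab)
    expect_gt(rates$mean_kg_ha_yr[rates$class == "small"],
              rates$mean_kg_ha_yr[rates$class == "large"])
  }
})
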