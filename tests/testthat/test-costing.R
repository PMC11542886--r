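# Equipment sizing, energy correlations and cost lines

test_that("reactor sizing follows flow x HRT with geometric wall scaling", {
  cfg <- system_config("fluidized_bed", hrt_d = 1)
  sz <- size_reactor(cfg, 50)
  expect_equal(sz$vessels$working_m3, 50)
  # packed bed at 16 h HRT: working volume 33.3 m3
  cfg2 <- system_config("packed_bed", hrt_d = 16 / 24)
  expect_equal(size_reactor(cfg2, 50)$vessels$working_m3, 100 / 3,
               tolerance = 1e-9)
  # doubling HRT doubles volume but wall material grows sublinearly
  cfg4 <- system_config("fluidized_bed", hrt_d = 2)
  sz4 <- size_reactor(cfg4, 50)
  expect_equal(sz4$vessels$working_m3, 100)
  conc <- function(s) s$takeoff$quantity[s$takeoff$item == "concrete"]
  expect_lt(conc(sz4) / conc(sz), 2)
  expect_gt(conc(sz4) / conc(sz), 1)
  expect_error(size_reactor(cfg, -5), "positive")
})

test_that("bead replacement schedule follows the ceiling rule", {
  mk <- function(life) system_config("packed_bed",
                                     bead = bead_spec(lifetime_yr = life))
  expect_equal(encapsulant_inventory(mk(1), 50)$batches, 30L)
  expect_equal(encapsulant_inventory(mk(10), 50)$batches, 3L)
  expect_equal(encapsulant_inventory(mk(30), 50)$batches, 1L)
  # property over a grid
  for (life in c(0.5, 2, 7, 12, 29, 31))
    expect_equal(encapsulant_inventory(mk(life), 50)$batches,
                 as.integer(ceiling(30 / life)))
  expect_error(encapsulant_inventory(system_config("UASB"), 50),
               "encapsulated")
})

test_that("encapsulant mass follows volume fraction and density", {
  cfg <- system_config("fluidized_bed", bead_volume_fraction = 0.25,
                       bead = bead_spec(density_kg_m3 = 1100))
  inv <- encapsulant_inventory(cfg, 100)
  expect_equal(inv$bead_volume_m3, 25)
  expect_equal(inv$peg_mass_kg, 25 * 1100)
  cfgp <- system_config("packed_bed", bed_voidage = 0.45)
  expect_equal(encapsulant_inventory(cfgp, 100)$bead_volume_m3, 55)
})

test_that("Wen-Yu fluidization velocity matches an independent evaluation", {
  b <- bead_spec(diameter_mm = 5, density_kg_m3 = 1050)
  fl <- fluidization_power(b, bed_area_m2 = 4, bed_height_m = 3,
                           volume_fraction = 0.25)
  # independent arithmetic: Ar and Re_mf evaluated from first principles
  d <- 5e-3; drho <- 50; mu <- 1e-3; rho <- 1000
  Ar <- rho * drho * 9.81 * d^3 / mu^2
  Re <- sqrt(33.7^2 + 0.0408 * Ar) - 33.7
  expect_equal(fl$u_mf_m_s, Re * mu / (rho * d), tolerance = 1e-6)
  # monotone increasing in bead diameter
  pw <- vapply(c(2, 5, 10), function(dd)
    fluidization_power(bead_spec(diameter_mm = dd, density_kg_m3 = 1100),
                       4, 3, 0.25)$power_kw, 0)
  expect_true(all(diff(pw) > 0))
  expect_error(
    fluidization_power(bead_spec(density_kg_m3 = 1000), 4, 3, 0.25),
    "exceed")
})

test_that("Ergun pressure drop: zero at rest, decreasing in voidage, textbook check", {
  expect_equal(packed_bed_pressure_drop(0.4, 5, 0), 0)
  expect_gt(packed_bed_pressure_drop(0.35, 5, 0.001),
            packed_bed_pressure_drop(0.45, 5, 0.001))
  # independent evaluation of both Ergun terms
  eps <- 0.45; d <- 2e-3; v <- 0.005
  ref <- 150 * 1e-3 * (1 - eps)^2 / (eps^3 * d^2) * v +
    1.75 * 1000 * (1 - eps) / (eps^3 * d) * v^2
  expect_equal(packed_bed_pressure_drop(eps, 2, v), ref, tolerance = 1e-6)
  expect_error(packed_bed_pressure_drop(1.1, 5, 0.01), "voidage")
})

test_that("heating duty arithmetic", {
  expect_equal(heating_duty(50, 22, 22)$duty_kw, 0)
  expect_equal(heating_duty(50, 22, 35, hx_effectiveness = 0)$duty_kw,
               1000 * 4.186 * 50 * 13 / 86400, tolerance = 1e-12)
  expect_equal(round(heating_duty(50, 22, 35, 0)$duty_kw, 1), 31.5)
  expect_equal(heating_duty(50, 22, 35, 0.5)$duty_kw,
               heating_duty(50, 22, 35, 0)$duty_kw / 2)
  expect_error(heating_duty(50, 22, 35, 1), "effectiveness")
})

test_that("cost lines apply power-law scaling and fail on missing items", {
  curves <- default_cost_curves()
  prices <- default_prices()
  zero_energy <- list(electricity_kwh_d = 0, natural_gas_mj_d = 0)
  empty <- cost_lines(tibble::tibble(item = character(),
                                     quantity = numeric(),
                                     unit = character()),
                      NULL, curves, zero_energy, prices)
  expect_equal(empty$capital_total, 0)
  expect_equal(empty$om_total_yr, 0)
  # single equipment item at base size: base cost x install factor
  eq <- tibble::tibble(item = "water_pump", size = 2)
  one <- cost_lines(tibble::tibble(item = character(), quantity = numeric(),
                                   unit = character()),
                    eq, curves, zero_energy, prices)
  row <- curves[curves$item == "water_pump", ]
  expect_equal(one$capital_total,
               row$base_cost_usd2021 * row$install_factor)
  # doubling size with exponent 0.6 scales cost by 2^0.6
  two <- cost_lines(tibble::tibble(item = character(), quantity = numeric(),
                                   unit = character()),
                    tibble::tibble(item = "water_pump", size = 4),
                    curves, zero_energy, prices)
  expect_equal(two$capital_total / one$capital_total, 2^0.6,
               tolerance = 1e-12)
  expect_equal(round(2^0.6, 3), 1.516)
  expect_error(
    cost_lines(tibble::tibble(item = "unobtainium", quantity = 1,
                              unit = "kg"),
               NULL, curves, zero_energy, prices),
    "unobtainium")
})

test_that("every cost line is nonnegative and totals equal the sum of lines", {
  r <- toy_small_result()
  ind <- compute_indicators(r)
  des <- anaerobead:::.design_scenario(r, default_cost_curves(),
                                       default_prices())
  cl <- cost_lines(des$takeoff, des$equipment, default_cost_curves(),
                   des$energy, default_prices(),
                   encapsulant = des$encapsulant)
  expect_true(all(cl$capital$cost_usd >= 0))
  expect_true(all(cl$om_annual$cost_usd_yr >= 0))
  expect_equal(cl$capital_total, sum(cl$capital$cost_usd))
  expect_equal(cl$om_total_yr, sum(cl$om_annual$cost_usd_yr))
})
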