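# ADM1 biokinetic core: stoichiometry, rates, pH closure, gas transfer and
# influent fractionation

test_that("stoichiometry conserves COD, carbon and nitrogen per process", {
  p <- adm1_params()
  nu <- adm1_stoichiometry(p)
  reg <- adm1_components()
  cod_bal <- colSums(nu * reg$cod)
  expect_lt(max(abs(cod_bal)), 1e-12)
  carbon <- reg$carbon; carbon[reg$name == "S_IC"] <- 1
  nitrogen <- reg$nitrogen; nitrogen[reg$name == "S_IN"] <- 1
  expect_lt(max(abs(colSums(nu * carbon))), 1e-12)
  expect_lt(max(abs(colSums(nu * nitrogen))), 1e-12)
})

test_that("acetoclastic uptake follows Monod with the half-saturation identity", {
  # inhibition disabled by construction: huge NH3 constant, tiny N half-sat
  p <- adm1_params(temperature_c = 35, K_I_nh3 = 1e6, K_S_IN = 1e-12)
  st <- adm1_state(S_ac = p$K_S_ac, X_ac = 2, S_IN = 0.05, S_cat = 0.1,
                   temperature_c = 35)
  r <- adm1_reaction_rates(st, p, ph = 7.8)
  # at S = K_S: uptake = k_m X / 2, of which (1 - Y) goes to methane
  rho_ac <- p$k_m_ac * 2 / 2
  expect_equal(unname(r["S_ch4"]), (1 - p$Y_ac) * rho_ac, tolerance = 1e-3)
  expect_equal(unname(r["S_ac"]), -rho_ac, tolerance = 1e-3)
})

test_that("zero substrate stops all uptakes; decay persists for biomass", {
  p <- adm1_params()
  st <- adm1_state(X_ac = 1, X_su = 2, S_IN = 0.01, S_cat = 0.05)
  r <- adm1_reaction_rates(st, p, ph = 7)
  dc <- exp(p$theta * (p$temperature_c - 35)) * p$k_dec
  expect_equal(unname(r["X_ac"]), -dc * 1, tolerance = 1e-12)
  expect_equal(unname(r["X_su"]), -dc * 2, tolerance = 1e-12)
  expect_equal(unname(r["X_c"]), dc * 3, tolerance = 1e-12)
  expect_equal(unname(r["S_ch4"]), 0)
  # all-zero state: nothing happens at all
  r0 <- adm1_reaction_rates(adm1_state(), p, ph = 7)
  expect_true(all(r0 == 0))
})

test_that("a hand-built single-guild Monod + decay balance matches", {
  # toy: only acetoclastic guild, hand-set parameters, arithmetic oracle
  p <- adm1_params(temperature_c = 35, k_m_ac = 10, K_S_ac = 0.2,
                   Y_ac = 0.05, k_dec = 0.03)
  S <- 0.6; X <- 3
  st <- adm1_state(S_ac = S, X_ac = X, S_IN = 1, S_cat = 0.2,
                   temperature_c = 35)
  r <- adm1_reaction_rates(st, p, ph = 7.6)
  sh <- 10^-7.6
  n <- 3 / (p$pH_UL_ac - p$pH_LL_ac)
  K <- 10^(-(p$pH_UL_ac + p$pH_LL_ac) / 2)
  I_ph <- K^n / (sh^n + K^n)
  I_in <- 1 / (1 + p$K_S_IN / 1)
  dcst <- anaerobead:::.derived_constants(p)
  nh3 <- 1 * dcst$Ka_IN / (dcst$Ka_IN + sh)
  I_nh3 <- 1 / (1 + nh3 / p$K_I_nh3)
  rho <- 10 * S / (S + 0.2) * X * I_ph * I_in * I_nh3
  expect_equal(unname(r["S_ac"]), -rho, tolerance = 1e-12)
  expect_equal(unname(r["S_ch4"]), (1 - 0.05) * rho, tolerance = 1e-12)
  expect_equal(unname(r["X_ac"]), 0.05 * rho - 0.03 * X, tolerance = 1e-12)
})

test_that("reaction_rates rejects invalid inputs", {
  st <- adm1_state(S_ac = 1)
  expect_error(adm1_reaction_rates(st, adm1_params(), ph = 15), "pH")
  expect_error(adm1_state(S_ac = -1), "nonnegative")
  expect_error(adm1_state(S_bogus = 1), "unknown component")
})

test_that("charge balance pH: pure water, strong base excess, monotonicity", {
  p <- adm1_params(temperature_c = 25)
  expect_equal(solve_ph(adm1_state(), p), 7, tolerance = 1e-3)
  # strong cation excess 1e-4, no buffers: h = Kw / cat -> pH 10
  st <- adm1_state(S_cat = 1e-4)
  h_exact <- (-1e-4 + sqrt(1e-8 + 4e-14)) / 2
  expect_equal(solve_ph(st, p), -log10(h_exact), tolerance = 1e-6)
  # increasing cations never decreases pH
  phs <- vapply(c(0, 1e-5, 1e-4, 1e-3, 1e-2),
                function(ct) solve_ph(adm1_state(S_cat = ct), p), 0)
  expect_true(all(diff(phs) >= 0))
})

test_that("solve_ph is deterministic and meets the charge-balance residual", {
  p <- adm1_params()
  set.seed(42)
  for (i in 1:20) {
    x <- adm1_state(S_ac = runif(1, 0, 3), S_pro = runif(1, 0, 1),
                    S_IC = runif(1, 0, 0.1), S_IN = runif(1, 0, 0.05),
                    S_cat = runif(1, 0, 0.1), S_an = runif(1, 0, 0.05))
    ph1 <- solve_ph(x, p)
    ph2 <- solve_ph(x, p)
    expect_identical(ph1, ph2)
    expect_gt(ph1, 0); expect_lt(ph1, 14)
  }
})

test_that("gas transfer is Henry-equilibrium driven with correct signs", {
  p <- adm1_params(temperature_c = 25)
  dc <- anaerobead:::.derived_constants(p)
  gas <- gas_phase(p_ch4 = 0.6, p_co2 = 0.3, p_h2 = 1e-5)
  eq_ch4 <- 64 * dc$KH_ch4 * 0.6
  st <- adm1_state(S_ch4 = eq_ch4, S_cat = 0.01)
  tr <- gas_transfer(st, gas, kLa = 100, p)
  expect_equal(unname(tr["ch4"]), 0, tolerance = 1e-10)
  expect_true(all(gas_transfer(st, gas, kLa = 0, p) == 0))
  st2 <- adm1_state(S_ch4 = 2 * eq_ch4, S_cat = 0.01)
  expect_gt(gas_transfer(st2, gas, kLa = 100, p)["ch4"], 0)
  expect_error(gas_transfer(st, gas, kLa = -1, p), "nonnegative")
  # colder water holds more methane at fixed partial pressure
  p_cold <- adm1_params(temperature_c = 15)
  dc_cold <- anaerobead:::.derived_constants(p_cold)
  expect_gt(dc_cold$KH_ch4, dc$KH_ch4)
})

test_that("a closed batch equilibrates dissolved CH4 to Henry's law", {
  p <- adm1_params(temperature_c = 25)
  dc <- anaerobead:::.derived_constants(p)
  gas <- gas_phase(p_ch4 = 0.7)
  kLa <- 50
  rhs <- function(t, y, parms) {
    st <- anaerobead:::.as_state(replace(unclass(adm1_state(S_cat = 0.01)),
                                         9, y[1]))
    list(-gas_transfer(st, gas, kLa, p)[["ch4"]])
  }
  out <- deSolve::lsoda(c(0.2), seq(0, 2, 0.5), rhs, NULL)
  final <- unname(out[nrow(out), 2])
  expect_equal(final, 64 * dc$KH_ch4 * 0.7, tolerance = 1e-3)
})

test_that("influent fractionation reproduces the COD pools exactly", {
  spec <- influent_spec()
  st <- fractionate_influent(spec)
  expect_equal(cod_of(st, "total"), 6.76, tolerance = 1e-9)
  expect_equal(cod_of(st, "soluble"), 5.64, tolerance = 1e-9)
  expect_equal(cod_of(st, "total") - cod_of(st, "soluble"), 1.12,
               tolerance = 1e-9)
  # soluble = total -> no particulates
  all_sol <- influent_spec(tcod_mg_l = 5000, scod_mg_l = 5000)
  st2 <- fractionate_influent(all_sol)
  expect_true(all(st2[anaerobead:::.particulate_idx] == 0))
  expect_error(influent_spec(scod_mg_l = 7000), "exceeds")
  expect_error(influent_spec(soluble_weights = c(S_su = 0.7)), "sum to 1")
})

test_that("cod_of applies the gas COD equivalents", {
  expect_equal(cod_of(adm1_state(), "total"), 0)
  # 1 mol CH4 per m3 = 0.064 kgCOD/m3; H2 16 g/mol
  st <- anaerobead:::.as_state(replace(unclass(adm1_state()), 9, 0.064))
  expect_equal(cod_of(st, "total"), 0.064)
  expect_equal(cod_of(fractionate_influent(influent_spec()), "total"), 6.76)
})

test_that("temperature correction scales biological rates exponentially", {
  p22 <- adm1_params(temperature_c = 22)
  p35 <- adm1_params(temperature_c = 35)
  st <- adm1_state(X_c = 1, S_IN = 0.01, S_cat = 0.05)
  r22 <- adm1_reaction_rates(st, p22, ph = 7)
  r35 <- adm1_reaction_rates(st, p35, ph = 7)
  expect_equal(unname(r22["X_c"] / r35["X_c"]), exp(0.069 * (22 - 35)),
               tolerance = 1e-10)
})
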