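# Radial diffusion-reaction in spherical hydrogel beads

test_that("specific interfacial area is 6 phi / d", {
  expect_equal(bead_interfacial_area(0.25, 5), 300)
  expect_equal(bead_interfacial_area(0, 5), 0)
  expect_equal(bead_interfacial_area(0.25, 2.5),
               2 * bead_interfacial_area(0.25, 5))
  expect_error(bead_interfacial_area(1.2, 5), "volume_fraction")
  expect_error(bead_interfacial_area(0.2, -1), "diameter")
})

test_that("shell geometry is consistent", {
  spec <- bead_spec(diameter_mm = 5, shell_count = 30)
  edges <- anaerobead:::.shell_edges(spec)
  vols <- anaerobead:::.shell_volumes(spec)
  expect_true(all(diff(edges) > 0))
  expect_equal(edges[length(edges)], 2.5e-3)
  expect_equal(sum(vols), 4 / 3 * pi * (2.5e-3)^3, tolerance = 1e-12)
  expect_error(bead_spec(shell_count = 2), "shell_count")
  expect_error(bead_spec(diffusivity_ratio = 1.5), "diffusivity_ratio")
})

test_that("uniform bead equal to bulk with no reaction is at equilibrium", {
  spec <- bead_spec(diameter_mm = 4, shell_count = 10)
  bulk <- adm1_state(S_ac = 1.5, S_su = 0.3, S_IC = 0.05, S_cat = 0.04)
  bs <- bead_state(spec, bulk)
  d <- bead_ode_rhs(bs, bulk, reactions = FALSE)
  expect_lt(max(abs(d$dCdt)), 1e-12)
  expect_lt(max(abs(d$surface_flux)), 1e-12)
})

test_that("transport is conservative: mass change equals surface flux x area", {
  spec <- bead_spec(diameter_mm = 4, shell_count = 12)
  bulk <- adm1_state(S_ac = 2, S_cat = 0.05)
  bs <- bead_state(spec, adm1_state(S_ac = 0.2, S_cat = 0.05))
  d <- bead_ode_rhs(bs, bulk, reactions = FALSE)
  vols <- bs$volumes
  mass_rate <- sum(sweep(d$dCdt, 2, vols, `*`))
  R <- spec$diameter_mm / 2000
  flux_total <- sum(d$surface_flux) * 4 * pi * R^2
  expect_equal(mass_rate, flux_total, tolerance = 1e-10)
})

test_that("effectiveness factor closed form behaves at its limits", {
  expect_equal(effectiveness_factor_linear(1e-8), 1, tolerance = 1e-6)
  expect_equal(effectiveness_factor_linear(1), 3 * (1 / tanh(1) - 1),
               tolerance = 1e-12)
  expect_equal(effectiveness_factor_linear(1), 0.9391, tolerance = 1e-4)
  # at phi = 100 the closed form sits exactly 1% under the 3/phi asymptote
  expect_equal(effectiveness_factor_linear(100), 3 / 100,
               tolerance = 1.5e-2)
  expect_error(effectiveness_factor_linear(-1), "nonnegative")
})

test_that("numerical bead solver reproduces the analytic effectiveness factor", {
  for (phi in c(0.1, 1, 3, 10)) {
    eta_num <- .linear_uptake_eta(phi, shells = 50)
    eta_ref <- effectiveness_factor_linear(phi)
    expect_lt(abs(eta_num - eta_ref) / eta_ref, 0.01)
  }
})

test_that("surface flux converges with second-order-like refinement", {
  fluxes <- vapply(c(25, 50, 100), function(s) .linear_uptake_eta(3, s), 0)
  d1 <- abs(fluxes[2] - fluxes[1])
  d2 <- abs(fluxes[3] - fluxes[2])
  expect_lt(d2 / d1, 0.5)
  expect_true(all(diff(fluxes) < 0) || all(diff(fluxes) > 0))
})

test_that("capacity cap clips overfull shells and books the excess as slough", {
  spec <- bead_spec(diameter_mm = 2, capacity_kgcod_m3 = 50, shell_count = 5)
  below <- bead_state(spec, adm1_state(X_ac = 30, S_cat = 0.05))
  r1 <- apply_capacity_cap(below)
  expect_identical(r1$state$C, below$C)
  expect_equal(r1$slough_kgcod_d, 0)

  over <- bead_state(spec, adm1_state(X_ac = 40, X_su = 20, S_cat = 0.05))
  r2 <- apply_capacity_cap(over, dt = 1)
  xtot <- colSums(r2$state$C[anaerobead:::.biomass_idx, ])
  expect_true(all(xtot <= 50 + 1e-12))
  # proportions preserved
  expect_equal(unname(r2$state$C["X_ac", 1] / r2$state$C["X_su", 1]), 2,
               tolerance = 1e-12)
  # excess mass balance: 10 kgCOD/m3 over cap, whole bead volume
  expect_equal(r2$slough_kgcod_d, 10 * sum(over$volumes), tolerance = 1e-12)
})

test_that("a strongly growing toy guild saturates the bead at the capacity", {
  # acetate-rich, fast-growing, slow-decay toy: growth outpaces decay
  # everywhere, so every shell should fill to the cap
  params <- adm1_params(temperature_c = 35, k_m_ac = 20, k_dec = 0.002,
                        K_I_nh3 = 1e6)
  influent <- influent_spec(flow_m3_d = 10, tcod_mg_l = 5000,
                            scod_mg_l = 5000,
                            soluble_weights = c(S_ac = 1))
  cfg <- system_config("fluidized_bed", hrt_d = 1, temperature_c = 35,
                       bead = bead_spec(diameter_mm = 1,
                                        diffusivity_ratio = 1,
                                        capacity_kgcod_m3 = 40,
                                        shell_count = 4),
                       bead_volume_fraction = 0.1)
  st <- sim_settings(shell_count = 4, x0_bead = 10,
                     inoculum_role = "acetoclastic",
                     t_chunk = 200, t_max = 8000)
  r <- simulate_scenario(cfg, influent, params, st)
  S <- 4
  shells <- matrix(r$state[30:(29 + 26 * S)], 26, S)
  xtot <- colSums(shells[anaerobead:::.biomass_idx, ])
  vols <- anaerobead:::.shell_volumes(cfg$bead)
  bead_biomass <- sum(xtot * vols)
  expect_equal(bead_biomass, 40 * sum(vols), tolerance = 5e-3)
  # the small encapsulated toy also fills its outer shells substantially
  res <- toy_small_result()
  toy <- make_toy_system("small")
  shells2 <- matrix(res$state[30:(29 + 26 * 4)], 26, 4)
  xtot2 <- colSums(shells2[anaerobead:::.biomass_idx, ])
  expect_lt(max(xtot2), toy$config$bead$capacity_kgcod_m3 * 1.005)
})
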