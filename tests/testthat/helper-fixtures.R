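# shared fixtures; expensive steady states are memoized across test files

.fx <- new.env(parent = emptyenv())

fast_settings <- function(...) {
  args <- list(shell_count = 4, t_chunk = 100, t_max = 4000)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_settings, args)
}

# a converged small encapsulated toy, reused by several files
toy_small_result <- function() {
  if (is.null(.fx$small)) {
    toy <- make_toy_system("small")
    .fx$small <- simulate_scenario(toy$config, toy$influent, toy$params,
                                   toy$settings)
  }
  .fx$small
}

# a converged default-influent UASB, cheap and tightly converged
uasb_result <- function(hrt_d = 1, retention_factor = 15) {
  key <- paste0("uasb_", hrt_d, "_", retention_factor)
  if (is.null(.fx[[key]])) {
    cfg <- system_config("UASB", hrt_d = hrt_d,
                         retention_factor = retention_factor)
    .fx[[key]] <- simulate_scenario(cfg, settings = fast_settings())
  }
  .fx[[key]]
}

# brute-force two-sample KS statistic: scan every breakpoint
ks_brute <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  Fa <- vapply(xs, function(x) mean(a <= x), 0)
  Fb <- vapply(xs, function(x) mean(b <= x), 0)
  max(abs(Fa - Fb))
}

# steady radial profile under first-order uptake, via the package transport
# operator plus a linear sink, integrated to steady state
.linear_uptake_eta <- function(phi_target, shells) {
  spec <- bead_spec(diameter_mm = 2, diffusivity_ratio = 1,
                    shell_count = shells)
  R <- spec$diameter_mm / 2000
  D <- anaerobead:::.default_aqueous_diffusivity()[["S_ac"]]
  k <- phi_target^2 * D / R^2            # phi = R sqrt(k / D)
  bulk <- adm1_state(S_ac = 1, S_cat = 0.05)
  i_ac <- anaerobead:::.cmp[["S_ac"]]
  rhs <- function(t, y, parms) {
    bs <- bead_state(spec, adm1_state(S_cat = 0.05))
    bs$C[i_ac, ] <- y
    d <- bead_ode_rhs(bs, bulk, reactions = FALSE)
    list(d$dCdt[i_ac, ] - k * y)
  }
  out <- deSolve::lsoda(rep(0, shells), c(0, 100 * R^2 / D), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  prof <- as.numeric(out[nrow(out), -1])
  bs <- bead_state(spec, adm1_state(S_cat = 0.05))
  bs$C[i_ac, ] <- prof
  d <- bead_ode_rhs(bs, bulk, reactions = FALSE)
  flux_in <- d$surface_flux[i_ac] * 4 * pi * R^2
  v_bead <- 4 / 3 * pi * R^3
  flux_in / (k * 1 * v_bead)             # actual / kinetics-limited uptake
}

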