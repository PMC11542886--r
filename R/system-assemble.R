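# Flowsheet assembly: state layout, initial condition and the reference
# right-hand side of the coupled bulk + bead + gas ODE system. A compiled
# mirror of this RHS (src/system_rhs.cpp) is used by the integrator; the two
# are held in lockstep by a parity test.

# overflow-safe smooth positive part, width w
.softplus <- function(x, w) ifelse(x / w > 30, x, w * log1p(exp(x / w)))

# per-stage state block: bulk(26) | gas(3) | shells(26 x S, column-major)
.stage_layout <- function(config, settings) {
  enc <- config$reactor_type != "UASB"
  S <- if (enc) settings$shell_count else 0L
  n_stage <- .n_cmp + 3L + .n_cmp * S
  list(encapsulated = enc, S = S, n_stage = n_stage,
       n_total = n_stage * config$stages)
}

#' Assemble a treatment scenario into a coupled ODE system
#'
#' Builds the full state layout, initial condition and right-hand side for a
#' configured flowsheet: one or two bulk CSTRs, each exchanging with a
#' radially discretized bead population through surface fluxes times the
#' specific interfacial area (encapsulated reactors), or with suspended
#' granular biomass retained by a three-phase separator (UASB). A two-stage
#' system chains the stage-1 effluent into stage 2; the stages are seeded
#' with fermenter-rich and methanogen-rich communities respectively.
#'
#' @param config A [system_config()].
#' @param influent An [influent_spec()].
#' @param params An [adm1_params()] set; its temperature is overridden by the
#'   configured operating temperature.
#' @param settings A [sim_settings()].
#' @return An `adm1_system` list with `y0`, `rhs` (function of `t`, `y`) and
#'   bookkeeping used by [integrate_to_steady_state()].
#' @export
assemble_system <- function(config, influent, params = adm1_params(),
                            settings = sim_settings()) {
  stopifnot(inherits(config, "system_config"),
            inherits(influent, "influent_spec"))
  params$temperature_c <- config$temperature_c
  lay <- .stage_layout(config, settings)
  Q <- influent$flow_m3_d
  c_in <- unclass(fractionate_influent(influent, config$temperature_c))

  stages <- vector("list", config$stages)
  splits <- if (config$stages == 2) c(config$hrt_split, 1 - config$hrt_split) else 1
  for (k in seq_len(config$stages)) {
    hrt <- config$hrt_d * splits[k]
    V <- Q * hrt
    phi <- .bead_fraction(config)
    V_liq <- V * (1 - phi)
    bead <- NULL
    if (lay$encapsulated) {
      bead <- config$bead
      bead$shell_count <- settings$shell_count
    }
    role <- if (!is.null(settings$inoculum_role)) settings$inoculum_role
            else if (config$stages == 1) "balanced"
            else if (k == 1) "fermenter" else "methanogen"
    stages[[k]] <- list(
      k = k, hrt = hrt, V = V, phi = phi, V_liq = V_liq,
      V_gas = settings$headspace_frac * V,
      bead = bead,
      area_m2 = if (lay$encapsulated)
        bead_interfacial_area(phi, bead$diameter_mm) * V else 0,
      n_beads = if (lay$encapsulated)
        phi * V / (4 / 3 * pi * (bead$diameter_mm / 2000)^3) else 0,
      role = role,
      # vacuum/membrane act on the first-stage reactor only
      p_set = if (k == 1 && config$h2_extraction == "vacuum")
        config$vacuum_bar else params$P_atm,
      mem_rate = if (k == 1 && config$h2_extraction == "membrane")
        settings$e_mem * config$membrane_recirc * Q else 0
    )
  }

  y0 <- numeric(lay$n_total)
  for (k in seq_len(config$stages)) {
    st <- stages[[k]]
    off <- (k - 1) * lay$n_stage
    bulk0 <- c_in
    bulk0[.soluble_idx] <- bulk0[.soluble_idx] * 0.5
    bulk0[.biomass_idx] <- if (lay$encapsulated)
      0.001 * settings$x0_bead * .guild_profile(st$role)
    else settings$x0_uasb * .guild_profile(st$role)
    y0[off + 1:.n_cmp] <- bulk0
    # headspace starts near atmospheric CH4/CO2 mix
    dc <- .derived_constants(params)
    p0 <- max(st$p_set - dc$p_h2o, 0.1)
    y0[off + .n_cmp + 1:3] <- c(1e-5 * 16 / (params$R_bar * dc$TK),
                                0.6 * p0 * 64 / (params$R_bar * dc$TK),
                                0.4 * p0 / (params$R_bar * dc$TK))
    if (lay$encapsulated) {
      shell0 <- bulk0
      shell0[.biomass_idx] <- settings$x0_bead * .guild_profile(st$role)
      y0[off + .n_cmp + 3 + seq_len(.n_cmp * lay$S)] <-
        rep(shell0, lay$S)
    }
  }

  sys <- structure(list(config = config, influent = influent, params = params,
                        settings = settings, layout = lay, stages = stages,
                        c_in = c_in, Q = Q, y0 = y0),
                   class = "adm1_system")
  sys$rhs <- if (settings$use_compiled) .make_rhs_compiled(sys)
             else function(t, y, p) list(.system_rhs_r(y, sys))
  sys
}

# reference implementation of the system right-hand side ---------------------

.system_rhs_r <- function(y, sys) {
  lay <- sys$layout
  params <- sys$params
  settings <- sys$settings
  dc <- .derived_constants(params)
  nu <- adm1_stoichiometry(params)
  D_aq <- .default_aqueous_diffusivity()
  dy <- numeric(length(y))
  c_in <- sys$c_in
  part_div_prev <- 1

  for (k in seq_len(sys$config$stages)) {
    st <- sys$stages[[k]]
    off <- (k - 1) * lay$n_stage
    bulk <- pmax(y[off + 1:.n_cmp], 0)
    gas <- pmax(y[off + .n_cmp + 1:3], 0)
    D <- sys$Q / st$V_liq

    # gas phase pressures
    p_h2 <- gas[1] * params$R_bar * dc$TK / 16
    p_ch4 <- gas[2] * params$R_bar * dc$TK / 64
    p_co2 <- gas[3] * params$R_bar * dc$TK
    P <- p_h2 + p_ch4 + p_co2 + dc$p_h2o

    ph_b <- .solve_ph_vec(matrix(bulk, ncol = 1), params)
    rho_b <- .process_rates(bulk, params, ph_b, dc$fT)
    react_b <- drop(nu %*% rho_b)

    sh <- 10^-ph_b
    s_co2 <- bulk[.cmp[["S_IC"]]] * sh / (sh + dc$Ka_co2)
    rT <- c(h2 = settings$kLa * (bulk[.cmp[["S_h2"]]] - 16 * dc$KH_h2 * p_h2),
            ch4 = settings$kLa * (bulk[.cmp[["S_ch4"]]] - 64 * dc$KH_ch4 * p_ch4),
            co2 = settings$kLa * (s_co2 - dc$KH_co2 * p_co2))

    # effluent particulate division by the separator / bed entrapment
    part_div <- .part_div(sys$config)

    inflow <- c_in
    if (k == 2) {
      prev <- pmax(y[1:.n_cmp], 0)
      inflow <- prev
      inflow[.particulate_idx] <- prev[.particulate_idx] / part_div_prev
    }
    part_div_prev <- part_div

    dbulk <- D * (inflow - bulk)
    dbulk[.particulate_idx] <- D * (inflow[.particulate_idx] -
                                      bulk[.particulate_idx] / part_div)
    dbulk <- dbulk + react_b
    dbulk[.cmp[["S_h2"]]] <- dbulk[.cmp[["S_h2"]]] - rT["h2"]
    dbulk[.cmp[["S_ch4"]]] <- dbulk[.cmp[["S_ch4"]]] - rT["ch4"]
    dbulk[.cmp[["S_IC"]]] <- dbulk[.cmp[["S_IC"]]] - rT["co2"]
    if (st$mem_rate > 0)
      dbulk[.cmp[["S_h2"]]] <- dbulk[.cmp[["S_h2"]]] -
        st$mem_rate / st$V_liq * bulk[.cmp[["S_h2"]]]

    # beads
    if (lay$encapsulated) {
      S <- lay$S
      C <- matrix(pmax(y[off + .n_cmp + 3 + seq_len(.n_cmp * S)], 0), .n_cmp, S)
      rownames(C) <- names(.cmp)
      tr <- .bead_diffusion(C, st$bead, bulk, D_aq)
      ph_s <- .solve_ph_vec(C, params)
      rho_s <- .process_rates(C, params, ph_s, dc$fT)
      dC <- tr$dCdt + nu %*% rho_s
      # encapsulation capacity: smooth overflow of gross growth to the bulk
      # crowding overflow: the exported fraction of gross growth rises as a
      # steep power of bead fullness, reaching 1 at the capacity and
      # exceeding it beyond, so shells equilibrate just below the cap
      cap <- st$bead$capacity_kgcod_m3
      xtot <- colSums(C[.biomass_idx, , drop = FALSE])
      sig <- (xtot / cap)^settings$cap_sharpness
      G <- rbind(params$Y_su * rho_s[5, ], params$Y_aa * rho_s[6, ],
                 params$Y_fa * rho_s[7, ],
                 params$Y_c4 * (rho_s[8, ] + rho_s[9, ]),
                 params$Y_pro * rho_s[10, ], params$Y_ac * rho_s[11, ],
                 params$Y_h2 * rho_s[12, ])
      divert <- sweep(G, 2, sig, `*`)
      dC[.biomass_idx, ] <- dC[.biomass_idx, ] - divert
      vols <- .shell_volumes(st$bead)
      slough <- drop(divert %*% vols) * st$n_beads / st$V_liq  # kg/m3liq/d
      dbulk[.biomass_idx] <- dbulk[.biomass_idx] + slough
      # inert disintegration residue has no in-bead sink; export it with the
      # slough stream so the bead interior admits a steady state
      prod_xi <- params$f_xI_xc * rho_s[1, ]
      dC[.cmp[["X_I"]], ] <- dC[.cmp[["X_I"]], ] - prod_xi
      dbulk[.cmp[["X_I"]]] <- dbulk[.cmp[["X_I"]]] +
        sum(prod_xi * vols) * st$n_beads / st$V_liq
      # bulk loses what diffuses into the beads
      exch <- tr$surface_flux * st$area_m2 / st$V_liq
      dbulk <- dbulk - exch
      dy[off + .n_cmp + 3 + seq_len(.n_cmp * S)] <- as.vector(dC)
    }

    # headspace: soft valve keeps pressure near its setpoint
    q_gas <- sys$settings$k_p * st$V_gas * .softplus(P - st$p_set, 1e-3)
    dgas <- c(rT["h2"], rT["ch4"], rT["co2"]) * st$V_liq / st$V_gas -
      gas * q_gas / st$V_gas
    dy[off + 1:.n_cmp] <- dbulk
    dy[off + .n_cmp + 1:3] <- dgas
  }
  dy
}

# flatten everything the compiled RHS needs into plain vectors
.cpp_pars <- function(sys) {
  params <- sys$params
  dc <- .derived_constants(params)
  lay <- sys$layout
  stg <- sys$stages
  list(
    n_stage = lay$n_stage, S = lay$S, stages = sys$config$stages,
    encapsulated = as.integer(lay$encapsulated),
    nu = adm1_stoichiometry(params),
    c_in = sys$c_in, Q = sys$Q,
    V_liq = vapply(stg, `[[`, 0, "V_liq"),
    V_gas = vapply(stg, `[[`, 0, "V_gas"),
    area = vapply(stg, `[[`, 0, "area_m2"),
    n_beads = vapply(stg, `[[`, 0, "n_beads"),
    p_set = vapply(stg, `[[`, 0, "p_set"),
    mem_rate = vapply(stg, `[[`, 0, "mem_rate"),
    part_div = .part_div(sys$config),
    kLa = sys$settings$kLa, k_p = sys$settings$k_p,
    cap_sharpness = sys$settings$cap_sharpness,
    cap = if (lay$encapsulated) sys$config$bead$capacity_kgcod_m3 else 0,
    shell_edges = if (lay$encapsulated) .shell_edges(stg[[1]]$bead) else numeric(),
    shell_vols = if (lay$encapsulated) .shell_volumes(stg[[1]]$bead) else numeric(),
    D_eff = if (lay$encapsulated)
      sys$config$bead$diffusivity_ratio * .default_aqueous_diffusivity()
      else numeric(),
    kin = unlist(params[c("k_dis", "k_hyd_ch", "k_hyd_pr", "k_hyd_li",
                          "k_m_su", "K_S_su", "k_m_aa", "K_S_aa",
                          "k_m_fa", "K_S_fa", "k_m_c4", "K_S_c4",
                          "k_m_pro", "K_S_pro", "k_m_ac", "K_S_ac",
                          "k_m_h2", "K_S_h2", "k_dec",
                          "Y_su", "Y_aa", "Y_fa", "Y_c4", "Y_pro", "Y_ac",
                          "Y_h2",
                          "K_S_IN", "K_I_h2_fa", "K_I_h2_c4", "K_I_h2_pro",
                          "K_I_nh3",
                          "pH_UL_aa", "pH_LL_aa", "pH_UL_ac", "pH_LL_ac",
                          "pH_UL_h2", "pH_LL_h2",
                          "Ka_va", "Ka_bu", "Ka_pro", "Ka_ac")]),
    fT = dc$fT,
    ab = c(Ka_co2 = dc$Ka_co2, Ka_IN = dc$Ka_IN, Kw = dc$Kw,
           KH_h2 = dc$KH_h2, KH_ch4 = dc$KH_ch4, KH_co2 = dc$KH_co2,
           p_h2o = dc$p_h2o, RT = params$R_bar * dc$TK)
  )
}

.make_rhs_compiled <- function(sys) {
  pars <- .cpp_pars(sys)
  function(t, y, p) list(system_rhs_cpp(y, pars))
}
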