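#' ADM1 stoichiometry matrix
#'
#' Builds the 26 x 19 stoichiometric matrix of the ADM1 biochemical network:
#' disintegration, three hydrolysis steps, eight substrate uptakes and seven
#' biomass decays. Inorganic carbon and nitrogen rows are closed by elemental
#' balance (their coefficients are minus the carbon/nitrogen content of all
#' other components in the process), so carbon and nitrogen are conserved
#' exactly and COD is conserved by construction of the product fractions.
#'
#' @param params An [adm1_params()] set.
#' @return A numeric matrix, rows named by component, columns by process.
#' @export
adm1_stoichiometry <- function(params = adm1_params()) {
  p <- params
  i <- .cmp
  nu <- matrix(0, .n_cmp, 19,
               dimnames = list(names(.cmp),
                               c("dis", "hyd_ch", "hyd_pr", "hyd_li",
                                 "up_su", "up_aa", "up_fa", "up_va", "up_bu",
                                 "up_pro", "up_ac", "up_h2",
                                 paste0("dec_", c("su", "aa", "fa", "c4",
                                                  "pro", "ac", "h2")))))
  # disintegration of composites
  nu[i["X_c"], "dis"] <- -1
  nu[i["S_I"], "dis"] <- p$f_sI_xc
  nu[i["X_I"], "dis"] <- p$f_xI_xc
  nu[i["X_ch"], "dis"] <- p$f_ch_xc
  nu[i["X_pr"], "dis"] <- p$f_pr_xc
  nu[i["X_li"], "dis"] <- p$f_li_xc
  # hydrolysis
  nu[i["X_ch"], "hyd_ch"] <- -1; nu[i["S_su"], "hyd_ch"] <- 1
  nu[i["X_pr"], "hyd_pr"] <- -1; nu[i["S_aa"], "hyd_pr"] <- 1
  nu[i["X_li"], "hyd_li"] <- -1
  nu[i["S_fa"], "hyd_li"] <- p$f_fa_li
  nu[i["S_su"], "hyd_li"] <- 1 - p$f_fa_li
  # uptakes: -1 substrate, (1-Y) products, Y biomass
  up <- function(proc, sub, prods, Y, guild) {
    nu[i[sub], proc] <<- -1
    for (nm in names(prods)) nu[i[nm], proc] <<- (1 - Y) * prods[[nm]]
    nu[i[guild], proc] <<- Y
  }
  up("up_su", "S_su",
     list(S_h2 = p$f_h2_su, S_bu = p$f_bu_su, S_pro = p$f_pro_su,
          S_ac = p$f_ac_su), p$Y_su, "X_su")
  up("up_aa", "S_aa",
     list(S_h2 = p$f_h2_aa, S_va = p$f_va_aa, S_bu = p$f_bu_aa,
          S_pro = p$f_pro_aa, S_ac = p$f_ac_aa), p$Y_aa, "X_aa")
  up("up_fa", "S_fa", list(S_ac = 0.7, S_h2 = 0.3), p$Y_fa, "X_fa")
  up("up_va", "S_va", list(S_pro = 0.54, S_ac = 0.31, S_h2 = 0.15),
     p$Y_c4, "X_c4")
  up("up_bu", "S_bu", list(S_ac = 0.8, S_h2 = 0.2), p$Y_c4, "X_c4")
  up("up_pro", "S_pro", list(S_ac = 0.57, S_h2 = 0.43), p$Y_pro, "X_pro")
  up("up_ac", "S_ac", list(S_ch4 = 1), p$Y_ac, "X_ac")
  up("up_h2", "S_h2", list(S_ch4 = 1), p$Y_h2, "X_h2")
  # decay: guild -> composite
  guilds <- c("X_su", "X_aa", "X_fa", "X_c4", "X_pro", "X_ac", "X_h2")
  for (k in seq_along(guilds)) {
    nu[i[guilds[k]], 12 + k] <- -1
    nu[i["X_c"], 12 + k] <- 1
  }
  # close carbon and nitrogen balances
  reg <- adm1_components()
  carbon <- reg$carbon; nitrogen <- reg$nitrogen
  carbon[i["S_IC"]] <- 0; nitrogen[i["S_IN"]] <- 0
  nu[i["S_IC"], ] <- -colSums(nu * carbon)
  nu[i["S_IN"], ] <- -colSums(nu * nitrogen)
  nu
}

# inhibition helpers ---------------------------------------------------------

.hill_ph <- function(sh, pH_UL, pH_LL) {
  # lower-pH inhibition switch, unity at high pH
  n <- 3 / (pH_UL - pH_LL)
  K <- 10^(-(pH_UL + pH_LL) / 2)
  K^n / (sh^n + K^n)
}

# biomass below this concentration (~single cells per m^3) cannot grow;
# keeps the sterile state exactly invariant under integrator roundoff
.x_extinct <- 1e-9

# process rate vector; C may be a matrix (components x volumes), ph a vector
.process_rates <- function(C, params, ph, fT = NULL) {
  p <- params
  if (is.null(dim(C))) C <- matrix(C, ncol = 1)
  if (is.null(fT)) fT <- .derived_constants(p)$fT
  C[.biomass_idx, ][C[.biomass_idx, ] < .x_extinct] <- 0
  i <- .cmp
  sh <- 10^(-ph)
  dc <- .derived_constants(p)
  S_nh3 <- C[i["S_IN"], ] * dc$Ka_IN / (dc$Ka_IN + sh)
  I_IN <- C[i["S_IN"], ] / (C[i["S_IN"], ] + p$K_S_IN)
  I_nh3 <- 1 / (1 + S_nh3 / p$K_I_nh3)
  I_h2 <- function(KI) 1 / (1 + C[i["S_h2"], ] / KI)
  I_aa <- .hill_ph(sh, p$pH_UL_aa, p$pH_LL_aa) * I_IN
  monod <- function(S, K) S / (S + K)
  rho <- matrix(0, 19, ncol(C))
  rho[1, ] <- p$k_dis * fT * C[i["X_c"], ]
  rho[2, ] <- p$k_hyd_ch * fT * C[i["X_ch"], ]
  rho[3, ] <- p$k_hyd_pr * fT * C[i["X_pr"], ]
  rho[4, ] <- p$k_hyd_li * fT * C[i["X_li"], ]
  rho[5, ] <- p$k_m_su * fT * monod(C[i["S_su"], ], p$K_S_su) * C[i["X_su"], ] * I_aa
  rho[6, ] <- p$k_m_aa * fT * monod(C[i["S_aa"], ], p$K_S_aa) * C[i["X_aa"], ] * I_aa
  rho[7, ] <- p$k_m_fa * fT * monod(C[i["S_fa"], ], p$K_S_fa) * C[i["X_fa"], ] *
    I_aa * I_h2(p$K_I_h2_fa)
  Sva <- C[i["S_va"], ]; Sbu <- C[i["S_bu"], ]
  comp <- Sva + Sbu + 1e-12
  rho[8, ] <- p$k_m_c4 * fT * monod(Sva, p$K_S_c4) * C[i["X_c4"], ] *
    (Sva / comp) * I_aa * I_h2(p$K_I_h2_c4)
  rho[9, ] <- p$k_m_c4 * fT * monod(Sbu, p$K_S_c4) * C[i["X_c4"], ] *
    (Sbu / comp) * I_aa * I_h2(p$K_I_h2_c4)
  rho[10, ] <- p$k_m_pro * fT * monod(C[i["S_pro"], ], p$K_S_pro) *
    C[i["X_pro"], ] * I_aa * I_h2(p$K_I_h2_pro)
  rho[11, ] <- p$k_m_ac * fT * monod(C[i["S_ac"], ], p$K_S_ac) * C[i["X_ac"], ] *
    .hill_ph(sh, p$pH_UL_ac, p$pH_LL_ac) * I_IN * I_nh3
  rho[12, ] <- p$k_m_h2 * fT * monod(C[i["S_h2"], ], p$K_S_h2) * C[i["X_h2"], ] *
    .hill_ph(sh, p$pH_UL_h2, p$pH_LL_h2) * I_IN
  for (k in 1:7) rho[12 + k, ] <- p$k_dec * fT * C[.biomass_idx[k], ]
  rho
}

#' Net ADM1 reaction rates at a point
#'
#' Evaluates the 19 biochemical process rates (first-order disintegration,
#' hydrolysis and decay; Monod uptakes with pH, hydrogen, ammonia and
#' nitrogen-limitation inhibition) and maps them through the stoichiometric
#' matrix to a net production rate per component.
#'
#' @param state An [adm1_state()].
#' @param params An [adm1_params()] set.
#' @param ph Liquid pH; if `NULL`, solved from the state's charge balance.
#' @return Named numeric vector of net rates, kg-COD m^-3 d^-1 (kmol for
#'   inorganic carbon/nitrogen).
#' @export
adm1_reaction_rates <- function(state, params = adm1_params(), ph = NULL) {
  state <- .as_state(state)
  if (any(state < 0)) stop("negative concentration in state")
  if (is.null(ph)) ph <- solve_ph(state, params)
  if (ph <= 0 || ph >= 14) stop("pH out of (0, 14)")
  nu <- adm1_stoichiometry(params)
  rho <- .process_rates(unclass(state), params, ph)
  drop(nu %*% rho)
}

#' Solve liquid pH from the charge balance
#'
#' Closes the acid-base system algebraically: given total VFA, inorganic
#' carbon, inorganic nitrogen and the strong ion pair, finds the proton
#' concentration at which the charge balance is zero. The balance is strictly
#' monotone in the proton concentration, so a safeguarded Newton iteration
#' converges from any bracket.
#'
#' @param state An [adm1_state()].
#' @param params An [adm1_params()] set (acid-base constants, temperature).
#' @return pH (dimensionless).
#' @export
solve_ph <- function(state, params = adm1_params()) {
  state <- .as_state(state)
  x <- unclass(state)
  drop(.solve_ph_vec(matrix(x, ncol = 1), params))
}

# vectorized charge-balance solve across columns of C
.solve_ph_vec <- function(C, params, sh0 = NULL) {
  dc <- .derived_constants(params)
  i <- .cmp
  p <- params
  f <- function(sh) {
    C[i["S_cat"], ] + C[i["S_IN"], ] * sh / (dc$Ka_IN + sh) + sh -
      C[i["S_an"], ] -
      C[i["S_IC"], ] * dc$Ka_co2 / (dc$Ka_co2 + sh) -
      (C[i["S_ac"], ] / 64) * p$Ka_ac / (p$Ka_ac + sh) -
      (C[i["S_pro"], ] / 112) * p$Ka_pro / (p$Ka_pro + sh) -
      (C[i["S_bu"], ] / 160) * p$Ka_bu / (p$Ka_bu + sh) -
      (C[i["S_va"], ] / 208) * p$Ka_va / (p$Ka_va + sh) -
      dc$Kw / sh
  }
  lo <- rep(1e-14, ncol(C)); hi <- rep(1, ncol(C))
  sh <- if (is.null(sh0)) rep(1e-7, ncol(C)) else pmin(pmax(sh0, 2 * lo), hi / 2)
  for (iter in 1:100) {
    fv <- f(sh)
    hi <- ifelse(fv > 0, sh, hi)
    lo <- ifelse(fv < 0, sh, lo)
    eps <- sh * 1e-6
    d <- (f(sh + eps) - fv) / eps
    shn <- sh - fv / d
    bad <- !is.finite(shn) | shn <= lo | shn >= hi
    shn[bad] <- sqrt(lo[bad] * hi[bad])
    if (all(abs(shn - sh) <= 1e-12 * sh)) { sh <- shn; break }
    sh <- shn
  }
  if (any(abs(f(sh)) > 1e-10))
    stop("charge balance did not converge to 1e-10 kmol/m3")
  -log10(sh)
}

#' Gas-liquid transfer rates
#'
#' Two-film transfer of H2, CH4 and CO2 between the bulk liquid and the
#' headspace, driven by the departure of the dissolved concentration from
#' Henry's-law equilibrium with the gas-phase partial pressure. Positive
#' rates are liquid-to-gas.
#'
#' @param state An [adm1_state()]; free CO2 is speciated from inorganic
#'   carbon at the state's charge-balance pH.
#' @param gas A [gas_phase()] state supplying partial pressures.
#' @param kLa Volumetric transfer coefficient, 1/d (applied to all species).
#' @param params An [adm1_params()] set.
#' @return Named vector `c(h2 = , ch4 = , co2 = )`; kg-COD m^-3 d^-1 for H2
#'   and CH4, kmol m^-3 d^-1 for CO2.
#' @export
gas_transfer <- function(state, gas, kLa, params = adm1_params()) {
  if (kLa < 0) stop("kLa must be nonnegative")
  state <- .as_state(state)
  dc <- .derived_constants(params)
  ph <- solve_ph(state, params)
  sh <- 10^-ph
  s_co2 <- state[["S_IC"]] * sh / (sh + dc$Ka_co2)
  c(h2 = kLa * (state[["S_h2"]] - 16 * dc$KH_h2 * gas$p_h2),
    ch4 = kLa * (state[["S_ch4"]] - 64 * dc$KH_ch4 * gas$p_ch4),
    co2 = kLa * (s_co2 - dc$KH_co2 * gas$p_co2))
}

#' Gas phase state
#'
#' @param p_h2,p_ch4,p_co2 Partial pressures, bar.
#' @param headspace_m3 Headspace volume, m^3.
#' @param outflow_nm3_d Gas outflow at the valve, Nm^3/d.
#' @param temperature_c Temperature, degrees Celsius.
#' @return A `gas_phase` list.
#' @export
gas_phase <- function(p_h2 = 0, p_ch4 = 0, p_co2 = 0, headspace_m3 = 1,
                      outflow_nm3_d = 0, temperature_c = 22) {
  stopifnot(p_h2 >= 0, p_ch4 >= 0, p_co2 >= 0, outflow_nm3_d >= 0,
            headspace_m3 > 0)
  structure(list(p_h2 = p_h2, p_ch4 = p_ch4, p_co2 = p_co2,
                 headspace_m3 = headspace_m3, outflow_nm3_d = outflow_nm3_d,
                 temperature_c = temperature_c),
            class = "gas_phase")
}
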