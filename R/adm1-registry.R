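#' ADM1 component registry
#'
#' The fixed ordering of the 26 liquid-phase state variables used throughout
#' the package: 12 soluble components, 12 particulate components and the
#' strong cation/anion pair. COD-carrying components are expressed in
#' kg-COD m^-3; inorganic carbon and nitrogen and the ion pair in kmol m^-3.
#'
#' @return A tibble with one row per component: `name`, `phase`
#'   (`"soluble"`/`"particulate"`/`"ion"`), `unit`, `cod` (1 if the component
#'   carries COD), `carbon` and `nitrogen` content (kmol per kg-COD, or per
#'   kmol for non-COD components).
#' @export
#' @examples
#' adm1_components()
adm1_components <- function() {
  tibble::tibble(
    name = c("S_su", "S_aa", "S_fa", "S_va", "S_bu", "S_pro", "S_ac",
             "S_h2", "S_ch4", "S_IC", "S_IN", "S_I",
             "X_c", "X_ch", "X_pr", "X_li", "X_su", "X_aa", "X_fa",
             "X_c4", "X_pro", "X_ac", "X_h2", "X_I",
             "S_cat", "S_an"),
    phase = c(rep("soluble", 12), rep("particulate", 12), rep("ion", 2)),
    unit = c(rep("kgCOD/m3", 9), "kmolC/m3", "kmolN/m3", "kgCOD/m3",
             rep("kgCOD/m3", 12), rep("kmol/m3", 2)),
    cod = c(rep(1, 9), 0, 0, 1, rep(1, 12), 0, 0),
    carbon = c(0.0313, 0.03, 0.0217, 0.024, 0.025, 0.0268, 0.0313,
               0, 0.0156, 1, 0, 0.03,
               0.02786, 0.0313, 0.03, 0.022, rep(0.0313, 7), 0.03,
               0, 0),
    nitrogen = c(0, 0.007, 0, 0, 0, 0, 0,
                 0, 0, 0, 1, 0.06 / 14,
                 0.0376 / 14, 0, 0.007, 0, rep(0.08 / 14, 7), 0.06 / 14,
                 0, 0)
  )
}

# index lookups used all over the internals; registry order is frozen
.cmp <- local({
  nm <- c("S_su", "S_aa", "S_fa", "S_va", "S_bu", "S_pro", "S_ac",
          "S_h2", "S_ch4", "S_IC", "S_IN", "S_I",
          "X_c", "X_ch", "X_pr", "X_li", "X_su", "X_aa", "X_fa",
          "X_c4", "X_pro", "X_ac", "X_h2", "X_I",
          "S_cat", "S_an")
  stats::setNames(seq_along(nm), nm)
})

.n_cmp <- 26L
.biomass_idx <- 17:23                      # the seven microbial guilds
.soluble_idx <- 1:12
.particulate_idx <- 13:24

# COD equivalents, kg-COD per kmol
.cod_per_kmol <- c(ch4 = 64, h2 = 16, ac = 64, pro = 112, bu = 160, va = 208)

#' Default ADM1 kinetic and physicochemical parameter set
#'
#' Returns the benchmark mesophilic (35 degC reference) ADM1 parameterization
#' as an editable named list. Biological rate constants are corrected to the
#' operating temperature with an exponential factor
#' `exp(theta * (T - 35))` and equilibrium/Henry constants with van't Hoff
#' expressions, so the same set serves both ambient (22 degC) and mesophilic
#' (35 degC) operation.
#'
#' @param temperature_c Operating temperature, degrees Celsius.
#' @param theta Temperature sensitivity of biological rates, 1/K.
#' @param ... Named overrides of any default entry (e.g. `k_m_ac = 10`).
#' @return An object of class `adm1_params`: a named list of rate constants,
#'   half-saturations, yields, product fractions, inhibition constants,
#'   acid-base and Henry parameters. All rates in 1/d, concentrations in
#'   kg-COD m^-3 or kmol m^-3.
#' @export
adm1_params <- function(temperature_c = 22, theta = 0.069, ...) {
  p <- list(
    temperature_c = temperature_c,
    theta = theta,
    # first-order steps
    k_dis = 0.5, k_hyd_ch = 10, k_hyd_pr = 10, k_hyd_li = 10,
    # Monod uptake maxima (kgCOD/kgCOD/d) and half saturations (kgCOD/m3)
    k_m_su = 30, K_S_su = 0.5,
    k_m_aa = 50, K_S_aa = 0.3,
    k_m_fa = 6, K_S_fa = 0.4,
    k_m_c4 = 20, K_S_c4 = 0.2,
    k_m_pro = 13, K_S_pro = 0.1,
    k_m_ac = 8, K_S_ac = 0.15,
    k_m_h2 = 35, K_S_h2 = 7e-6,
    k_dec = 0.02,
    # yields (kgCOD biomass / kgCOD substrate)
    Y_su = 0.10, Y_aa = 0.08, Y_fa = 0.06, Y_c4 = 0.06,
    Y_pro = 0.04, Y_ac = 0.05, Y_h2 = 0.06,
    # disintegration / product fractions
    f_sI_xc = 0.1, f_xI_xc = 0.2, f_ch_xc = 0.2, f_pr_xc = 0.2, f_li_xc = 0.3,
    f_fa_li = 0.95,
    f_h2_su = 0.19, f_bu_su = 0.13, f_pro_su = 0.27, f_ac_su = 0.41,
    f_h2_aa = 0.06, f_va_aa = 0.23, f_bu_aa = 0.26, f_pro_aa = 0.05,
    f_ac_aa = 0.40,
    # inhibition
    K_S_IN = 1e-4,
    K_I_h2_fa = 5e-6, K_I_h2_c4 = 1e-5, K_I_h2_pro = 3.5e-6,
    K_I_nh3 = 0.0018,
    pH_UL_aa = 5.5, pH_LL_aa = 4,
    pH_UL_ac = 7, pH_LL_ac = 6,
    pH_UL_h2 = 6, pH_LL_h2 = 5,
    # acid-base at 298.15 K with van't Hoff enthalpies (J/mol)
    Ka_va = 10^-4.86, Ka_bu = 10^-4.82, Ka_pro = 10^-4.88, Ka_ac = 10^-4.76,
    Ka_co2 = 10^-6.35, dH_Ka_co2 = 7646,
    Ka_IN = 10^-9.25, dH_Ka_IN = 51965,
    Kw = 1e-14, dH_Kw = 55900,
    # Henry constants at 298.15 K, kmol m^-3 bar^-1, with dissolution enthalpies
    KH_h2 = 7.8e-4, dH_KH_h2 = -4180,
    KH_ch4 = 1.4e-3, dH_KH_ch4 = -14240,
    KH_co2 = 3.5e-2, dH_KH_co2 = -19410,
    # gas-liquid transfer and gas phase
    kLa = 200, P_atm = 1.013, R_bar = 0.083145
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown ADM1 parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(
    p$k_dis > 0, p$K_S_ac > 0, p$k_m_ac > 0,
    all(unlist(p[c("Y_su", "Y_aa", "Y_fa", "Y_c4", "Y_pro", "Y_ac", "Y_h2")]) > 0),
    all(unlist(p[c("Y_su", "Y_aa", "Y_fa", "Y_c4", "Y_pro", "Y_ac", "Y_h2")]) < 1)
  )
  structure(p, class = "adm1_params")
}

# temperature-corrected derived constants, bundled once per simulation
.derived_constants <- function(params) {
  TK <- params$temperature_c + 273.15
  Tref <- 298.15
  vh <- function(k, dH) k * exp(dH / 8.314 * (1 / Tref - 1 / TK))
  fT <- exp(params$theta * (params$temperature_c - 35))
  list(
    TK = TK,
    fT = fT,
    Ka_co2 = vh(params$Ka_co2, params$dH_Ka_co2),
    Ka_IN = vh(params$Ka_IN, params$dH_Ka_IN),
    Kw = vh(params$Kw, params$dH_Kw),
    # dH of dissolution is negative: colder water dissolves more gas
    KH_h2 = vh(params$KH_h2, params$dH_KH_h2),
    KH_ch4 = vh(params$KH_ch4, params$dH_KH_ch4),
    KH_co2 = vh(params$KH_co2, params$dH_KH_co2),
    p_h2o = 0.0313 * exp(5290 * (1 / 298.15 - 1 / TK))
  )
}

#' Construct an ADM1 state vector
#'
#' @param ... Named component concentrations (see [adm1_components()] for
#'   names and units); unnamed components default to zero.
#' @param temperature_c Temperature carried with the state, degrees Celsius.
#' @return A named numeric vector of length 26 with class `adm1_state`.
#' @export
#' @examples
#' adm1_state(S_ac = 1, X_ac = 0.5)
adm1_state <- function(..., temperature_c = 22) {
  x <- stats::setNames(numeric(.n_cmp), names(.cmp))
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(.cmp))
    if (length(bad)) stop("unknown component(s): ", paste(bad, collapse = ", "))
    x[names(dots)] <- dots
  }
  if (any(x < 0)) stop("concentrations must be nonnegative")
  structure(x, temperature_c = temperature_c, class = "adm1_state")
}

#' @export
print.adm1_state <- function(x, ...) {
  cat("<adm1_state>  T =", attr(x, "temperature_c"), "degC\n")
  nz <- x[x != 0]
  if (length(nz)) print(unclass(nz)) else cat("(all zero)\n")
  invisible(x)
}

.as_state <- function(x, temperature_c = 22) {
  if (inherits(x, "adm1_state")) return(x)
  stopifnot(is.numeric(x), length(x) == .n_cmp)
  structure(stats::setNames(as.numeric(x), names(.cmp)),
            temperature_c = temperature_c, class = "adm1_state")
}

#' Chemical oxygen demand of a state
#'
#' Sums the COD-carrying components of an ADM1 state on the requested basis.
#' Dissolved methane and hydrogen are already expressed in COD units
#' (64 g-COD/mol CH4, 16 g-COD/mol H2 were used in the conversion).
#'
#' @param state An [adm1_state()].
#' @param basis `"total"` or `"soluble"`.
#' @return COD concentration, kg m^-3.
#' @export
cod_of <- function(state, basis = c("total", "soluble")) {
  basis <- match.arg(basis)
  state <- .as_state(state)
  cod <- adm1_components()$cod
  idx <- if (basis == "soluble") .soluble_idx else seq_len(.n_cmp)
  sum(state[idx] * cod[idx])
}
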