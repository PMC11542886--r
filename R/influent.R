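#' Influent wastewater specification
#'
#' Describes a steady influent stream by flow, total and soluble COD, and the
#' fractionation weights that map the two COD pools onto ADM1 components.
#' The default weights describe a carbohydrate-rich high-strength brewery
#' stream: most soluble COD as sugars with amino acids, long-chain fatty
#' acids, VFAs and a small inert share; all particulate COD enters as
#' composite material.
#'
#' @param flow_m3_d Flow, m^3/d.
#' @param tcod_mg_l Total COD, mg/L.
#' @param scod_mg_l Soluble COD, mg/L (must not exceed total).
#' @param soluble_weights Named nonnegative weights over soluble COD
#'   components, summing to 1.
#' @param particulate_weights Named nonnegative weights over particulate COD
#'   components, summing to 1.
#' @param s_IN,s_IC,s_cat,s_an Inorganic nitrogen/carbon and strong ion
#'   concentrations, kmol/m^3.
#' @return An `influent_spec` list.
#' @export
#' @examples
#' influent_spec()  # the default brewery stream
influent_spec <- function(flow_m3_d = 50, tcod_mg_l = 6760, scod_mg_l = 5640,
                          soluble_weights = c(S_su = 0.5, S_aa = 0.2,
                                              S_fa = 0.05, S_ac = 0.1,
                                              S_pro = 0.05, S_bu = 0.05,
                                              S_I = 0.05),
                          particulate_weights = c(X_c = 1),
                          s_IN = 0.01, s_IC = 0.05,
                          s_cat = 0.08, s_an = 0.02) {
  if (scod_mg_l > tcod_mg_l) stop("soluble COD exceeds total COD")
  if (flow_m3_d <= 0) stop("flow must be positive")
  chk <- function(w, pool, allowed) {
    if (any(w < 0)) stop(pool, " weights must be nonnegative")
    if (abs(sum(w) - 1) > 1e-9) stop(pool, " weights must sum to 1")
    bad <- setdiff(names(w), allowed)
    if (length(bad)) stop("not a ", pool, " COD component: ",
                          paste(bad, collapse = ", "))
  }
  reg <- adm1_components()
  chk(soluble_weights, "soluble",
      reg$name[reg$phase == "soluble" & reg$cod == 1])
  chk(particulate_weights, "particulate",
      reg$name[reg$phase == "particulate" & reg$cod == 1])
  structure(list(flow_m3_d = flow_m3_d, tcod_mg_l = tcod_mg_l,
                 scod_mg_l = scod_mg_l,
                 soluble_weights = soluble_weights,
                 particulate_weights = particulate_weights,
                 s_IN = s_IN, s_IC = s_IC, s_cat = s_cat, s_an = s_an),
            class = "influent_spec")
}

#' Fractionate an influent specification into an ADM1 state
#'
#' Distributes the soluble COD pool over soluble ADM1 components and the
#' particulate pool (total minus soluble COD) over particulate components
#' according to the specification's weights; inorganic species are copied
#' through. The returned state reproduces the specified total and soluble
#' COD exactly.
#'
#' @param spec An [influent_spec()].
#' @param temperature_c Temperature attached to the state.
#' @return An [adm1_state()] in kg-COD m^-3 / kmol m^-3.
#' @export
fractionate_influent <- function(spec, temperature_c = 22) {
  stopifnot(inherits(spec, "influent_spec"))
  scod <- spec$scod_mg_l / 1000          # kg/m3
  pcod <- (spec$tcod_mg_l - spec$scod_mg_l) / 1000
  x <- stats::setNames(numeric(.n_cmp), names(.cmp))
  x[names(spec$soluble_weights)] <- scod * spec$soluble_weights
  x[names(spec$particulate_weights)] <-
    x[names(spec$particulate_weights)] + pcod * spec$particulate_weights
  x["S_IN"] <- spec$s_IN; x["S_IC"] <- spec$s_IC
  x["S_cat"] <- spec$s_cat; x["S_an"] <- spec$s_an
  .as_state(x, temperature_c = temperature_c)
}

#' COD mass flow of an influent stream
#'
#' @param spec An [influent_spec()].
#' @return Total COD load, kg/d.
#' @export
influent_cod_load <- function(spec) {
  spec$flow_m3_d * spec$tcod_mg_l / 1000
}
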