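# Generators and fixtures: the case-study influent stream, reduced toy systems
# with accelerated kinetics for fast tests, and the per-reactor-type
# 18-parameter uncertainty spaces (editable defaults standing in for the
# unavailable literature table).

#' Brewery influent generator
#'
#' The default case-study stream: 50 m^3/d of high-strength brewery wastewater with a
#' total COD of 6760 mg/L and a soluble COD of 5640 mg/L.
#'
#' @param flow_m3_d Flow, m^3/d. @param tcod_mg_l Total COD, mg/L.
#' @param scod_mg_l Soluble COD, mg/L.
#' @param ... Passed to [influent_spec()] (fractionation weights, inorganic
#'   species).
#' @return An [influent_spec()].
#' @export
#' @examples
#' influent_cod_load(make_influent())   # 338 kg COD per day
make_influent <- function(flow_m3_d = 50, tcod_mg_l = 6760,
                          scod_mg_l = 5640, ...) {
  if (scod_mg_l > tcod_mg_l) stop("soluble COD exceeds total COD")
  influent_spec(flow_m3_d = flow_m3_d, tcod_mg_l = tcod_mg_l,
                scod_mg_l = scod_mg_l, ...)
}

#' Toy scenarios with accelerated kinetics
#'
#' Reduced systems whose steady states converge in seconds, used throughout
#' the test-suite. `"tiny"` is a single-guild acetate-only chemostat (a UASB
#' with retention factor 1 seeded with acetoclastic methanogens only) whose
#' washout boundary has the closed chemostat form; `"small"` is a
#' single-stage fluidized bed with few shells.
#'
#' @param scale `"tiny"` or `"small"`.
#' @param hrt_d Hydraulic retention time of the toy, d (the tiny chemostat
#'   washes out when `1/hrt_d` exceeds `Y_ac k_m_ac - k_dec`, about 0.38/d
#'   at mesophilic defaults).
#' @return List with `config`, `influent`, `params`, `settings`.
#' @export
make_toy_system <- function(scale = c("tiny", "small"),
                            hrt_d = if (match.arg(scale) == "tiny") 5 else 2) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    # strongly buffered acetate feed: pH sits on the flat part of the
    # inhibition curves, and ammonia inhibition is disabled, so the washout
    # boundary keeps the clean chemostat closed form
    influent <- influent_spec(flow_m3_d = 10, tcod_mg_l = 3000,
                              scod_mg_l = 3000,
                              soluble_weights = c(S_ac = 1),
                              s_cat = 0.15)
    params <- adm1_params(temperature_c = 35, K_I_nh3 = 1e6)
    config <- system_config("UASB", hrt_d = hrt_d, temperature_c = 35,
                            retention_factor = 1)
    settings <- sim_settings(x0_uasb = 2, inoculum_role = "acetoclastic",
                             t_chunk = 100, t_max = 3000)
  } else {
    influent <- influent_spec(flow_m3_d = 10, tcod_mg_l = 4000,
                              scod_mg_l = 3600)
    params <- adm1_params(temperature_c = 35)
    config <- system_config("fluidized_bed", hrt_d = hrt_d,
                            temperature_c = 35,
                            bead = bead_spec(diameter_mm = 2,
                                             capacity_kgcod_m3 = 60,
                                             shell_count = 4),
                            bead_volume_fraction = 0.2)
    settings <- sim_settings(shell_count = 4, x0_bead = 15,
                             t_chunk = 100, t_max = 3000)
  }
  list(config = config, influent = influent, params = params,
       settings = settings)
}

#' Default 18-parameter uncertainty space
#'
#' Distribution families and bounds for the Monte Carlo analysis of each
#' reactor type: the key decision variables (uniform, full control within a
#' feasible range), six sensitive ADM1 kinetic constants, and
#' configuration-specific technological parameters. The exact literature
#' table is not bundled; these are documented editable defaults.
#'
#' @param reactor_type `"fluidized_bed"`, `"packed_bed"` or `"UASB"`.
#' @return A tibble: `name`, `kind` (decision/kinetic/technology), `dist`,
#'   `min`, `max`, `mode`, `unit`.
#' @export
make_parameter_space <- function(reactor_type = c("fluidized_bed",
                                                  "packed_bed", "UASB")) {
  reactor_type <- match.arg(reactor_type)
  row <- function(name, kind, dist, min, max, mode = NA_real_, unit = "") {
    tibble::tibble(name = name, kind = kind, dist = dist, min = min,
                   max = max, mode = mode, unit = unit)
  }
  common <- dplyr::bind_rows(
    row("hrt_d", "decision", "uniform", 4 / 24, 5, unit = "d"),
    row("k_dis", "kinetic", "uniform", 0.25, 1.0, unit = "1/d"),
    row("k_hyd_ch", "kinetic", "uniform", 5, 15, unit = "1/d"),
    row("k_m_ac", "kinetic", "uniform", 4, 16, unit = "COD/COD/d"),
    row("K_S_ac", "kinetic", "uniform", 0.05, 0.30, unit = "kgCOD/m3"),
    row("k_m_pro", "kinetic", "uniform", 6, 20, unit = "COD/COD/d"),
    row("k_m_h2", "kinetic", "uniform", 17, 50, unit = "COD/COD/d"),
    row("influent_tcod_mg_l", "technology", "triangle", 6000, 7400,
        mode = 6760, unit = "mg/L"),
    row("degas_efficiency", "technology", "uniform", 0.70, 0.95))
  bead_tech <- dplyr::bind_rows(
    row("bead_diameter_mm", "technology", "uniform", 1, 5, unit = "mm"),
    row("bead_lifetime_yr", "technology", "uniform", 1, 30, unit = "yr"),
    row("diffusivity_ratio", "technology", "uniform", 0.2, 1.0),
    row("capacity_kgcod_m3", "technology", "uniform", 50, 200,
        unit = "kgCOD/m3"),
    row("bead_density_kg_m3", "technology", "uniform", 1050, 1200,
        unit = "kg/m3"),
    row("peg_price_usd_kg", "technology", "uniform", 6, 12, unit = "USD/kg"),
    row("peg_gwp_kg", "technology", "uniform", 2, 4, unit = "kgCO2e/kg"),
    row("electricity_price_usd_kwh", "technology", "uniform", 0.06, 0.12,
        unit = "USD/kWh"))
  out <- switch(reactor_type,
    fluidized_bed = dplyr::bind_rows(
      common,
      row("bead_volume_fraction", "decision", "uniform", 0.03, 0.25),
      bead_tech),
    packed_bed = dplyr::bind_rows(
      common,
      row("bed_voidage", "decision", "uniform", 0.35, 0.45),
      bead_tech),
    UASB = dplyr::bind_rows(
      common,
      row("retention_factor", "technology", "uniform", 5, 30),
      row("kLa", "technology", "uniform", 100, 300, unit = "1/d"),
      row("electricity_price_usd_kwh", "technology", "uniform", 0.06, 0.12,
          unit = "USD/kWh"),
      row("natural_gas_price_usd_mj", "technology", "uniform", 0.003, 0.008,
          unit = "USD/MJ"),
      row("maintenance_frac", "technology", "uniform", 0.015, 0.04),
      row("ch4_gwp", "technology", "uniform", 24, 32, unit = "kgCO2e/kg"),
      row("influent_scod_frac", "technology", "uniform", 0.75, 0.90),
      row("influent_flow_m3_d", "technology", "uniform", 40, 60,
          unit = "m3/d"),
      row("discount_rate", "technology", "uniform", 0.03, 0.07)))
  stopifnot(nrow(out) == 18, all(out$max > out$min))
  out
}

#' Shared sample matrix across encapsulated reactor types
#'
#' Samples the union of the fluidized-bed and packed-bed parameter spaces
#' once, so identical draws can be applied to both reactor types for paired
#' comparison.
#'
#' @param n Number of samples. @param seed Integer seed.
#' @return A tibble of samples covering both spaces.
#' @export
shared_stage2_samples <- function(n, seed = 1) {
  fl <- make_parameter_space("fluidized_bed")
  pb <- make_parameter_space("packed_bed")
  un <- dplyr::distinct(dplyr::bind_rows(fl, pb), .data$name,
                        .keep_all = TRUE)
  lhs_sample(un, n, seed)
}

#' Instantiate scenario inputs from one uncertainty sample
#'
#' Maps a named sample row onto the configuration, kinetic parameters,
#' simulator settings, cost/impact tables and prices used by
#' [evaluate_scenario()]. Parameters absent from the row keep their
#' defaults; parameters inapplicable to the reactor type are ignored.
#'
#' @param row One-row tibble (or named list) of sampled parameter values.
#' @param reactor_type Target reactor type.
#' @param settings Base [sim_settings()].
#' @return List with `config`, `influent`, `params`, `settings`, `curves`,
#'   `factors`, `prices`.
#' @export
apply_sample <- function(row, reactor_type, settings = sim_settings()) {
  g <- function(nm, default) if (!is.null(row[[nm]]) && !is.na(row[[nm]]))
    row[[nm]] else default
  influent <- make_influent(
    flow_m3_d = g("influent_flow_m3_d", 50),
    tcod_mg_l = g("influent_tcod_mg_l", 6760),
    scod_mg_l = g("influent_scod_frac", 5640 / 6760) *
      g("influent_tcod_mg_l", 6760))
  params <- adm1_params(
    k_dis = g("k_dis", 0.5), k_hyd_ch = g("k_hyd_ch", 10),
    k_m_ac = g("k_m_ac", 8), K_S_ac = g("K_S_ac", 0.15),
    k_m_pro = g("k_m_pro", 13), k_m_h2 = g("k_m_h2", 35),
    kLa = g("kLa", 200))
  settings$kLa <- g("kLa", settings$kLa)
  settings$degas_efficiency <- g("degas_efficiency",
                                 settings$degas_efficiency)
  bead <- NULL
  if (reactor_type != "UASB")
    bead <- bead_spec(
      diameter_mm = g("bead_diameter_mm", 5),
      diffusivity_ratio = g("diffusivity_ratio", 0.5),
      capacity_kgcod_m3 = g("capacity_kgcod_m3", 100),
      lifetime_yr = g("bead_lifetime_yr", 10),
      density_kg_m3 = g("bead_density_kg_m3", 1100),
      shell_count = settings$shell_count)
  config <- system_config(
    reactor_type, stages = 1, temperature_c = 22,
    hrt_d = g("hrt_d", 1), h2_extraction = "passive", degassing = TRUE,
    bead = bead,
    bead_volume_fraction = if (reactor_type == "fluidized_bed")
      g("bead_volume_fraction", 0.25),
    bed_voidage = if (reactor_type == "packed_bed") g("bed_voidage", 0.4),
    retention_factor = g("retention_factor", 15))
  curves <- default_cost_curves()
  curves$base_cost_usd2021[curves$item == "peg_encapsulant"] <-
    g("peg_price_usd_kg", 9.0)
  factors <- default_impact_factors(ch4_gwp = g("ch4_gwp", 28))
  factors$factor[factors$flow == "peg_encapsulant"] <- g("peg_gwp_kg", 3.0)
  attr(factors, "checksum") <- sum(factors$factor * seq_len(nrow(factors)))
  prices <- default_prices(
    electricity_usd_kwh = g("electricity_price_usd_kwh", 0.0845),
    natural_gas_usd_mj = g("natural_gas_price_usd_mj", 0.005),
    maintenance_frac = g("maintenance_frac", 0.025))
  list(config = config, influent = influent, params = params,
       settings = settings, curves = curves, factors = factors,
       prices = prices, discount_rate = g("discount_rate", 0.05))
}

#' Run the Monte Carlo uncertainty stage for one reactor type
#'
#' Evaluates every sample row to steady state (warm-started within the
#' batch) and returns the five indicators per sample: rCOD and the
#' levelized cost and carbon intensity with and without effluent degassing.
#'
#' @param samples A sample tibble (e.g. [shared_stage2_samples()]).
#' @param reactor_type Reactor type to evaluate.
#' @param settings Base simulator settings.
#' @param progress Print progress every so many samples (0 = quiet).
#' @return Tibble: one row per sample with `rcod`, `lc_degas`,
#'   `lc_no_degas`, `ci_degas`, `ci_no_degas`, `converged`.
#' @export
run_stage2 <- function(samples, reactor_type, settings = sim_settings(),
                       progress = 0) {
  y_warm <- NULL
  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    inp <- apply_sample(samples[i, ], reactor_type, settings)
    sys <- assemble_system(inp$config, inp$influent, inp$params,
                           inp$settings)
    res <- integrate_to_steady_state(sys, y0 = y_warm)
    if (res$converged) y_warm <- res$state
    ind_d <- compute_indicators(res, degassing = TRUE, curves = inp$curves,
                                factors = inp$factors, prices = inp$prices,
                                discount_rate = inp$discount_rate)
    ind_n <- compute_indicators(res, degassing = FALSE, curves = inp$curves,
                                factors = inp$factors, prices = inp$prices,
                                discount_rate = inp$discount_rate)
    out[[i]] <- tibble::tibble(
      sample_id = i, rcod = ind_d$rcod,
      lc_degas = ind_d$lc_usd_t, lc_no_degas = ind_n$lc_usd_t,
      ci_degas = ind_d$ci_kgco2_t, ci_no_degas = ind_n$ci_kgco2_t,
      converged = res$converged)
    if (progress > 0 && i %% progress == 0)
      message(sprintf("%s sample %d/%d", reactor_type, i, nrow(samples)))
  }
  dplyr::bind_rows(out)
}

#' Carbon-intensity evaluator for the stage-III design maps
#'
#' Returns a closure `(par, dv)` for [stage3_map()] that simulates the
#' configured reactor type at 1 mm bead size with the supplied technology
#' parameters (e.g. `bead_lifetime_yr`, `k_m_ac`, `diffusivity_ratio`) and
#' decision variables (`hrt_d` and, for fluidized beds,
#' `bead_volume_fraction`), warm-starting consecutive simulations.
#'
#' @param reactor_type `"fluidized_bed"` or `"packed_bed"`.
#' @param settings Simulator settings for the map.
#' @param bed_voidage Packed-bed voidage (loose packing 0.45).
#' @param bead_diameter_mm Bead size used for the maps.
#' @return A function `(par, dv) -> list(ci, lc, rcod)`.
#' @export
stage3_ci_evaluator <- function(reactor_type, settings = sim_settings(),
                                bed_voidage = 0.45, bead_diameter_mm = 1) {
  cache <- new.env(parent = emptyenv())
  function(par, dv) {
    row <- c(as.list(par), as.list(dv),
             list(bead_diameter_mm = bead_diameter_mm))
    if (reactor_type == "packed_bed") row$bed_voidage <- bed_voidage
    inp <- apply_sample(row, reactor_type, settings)
    sys <- assemble_system(inp$config, inp$influent, inp$params,
                           inp$settings)
    res <- integrate_to_steady_state(sys, y0 = cache$y)
    if (res$converged) cache$y <- res$state
    ind <- compute_indicators(res, degassing = TRUE, curves = inp$curves,
                              factors = inp$factors, prices = inp$prices,
                              discount_rate = inp$discount_rate)
    list(ci = ind$ci_kgco2_t, lc = ind$lc_usd_t, rcod = ind$rcod,
         converged = res$converged)
  }
}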