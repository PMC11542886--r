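# Equipment sizing, material takeoffs, energy demands and cost line items.
# All coefficients live in editable tables (inst/extdata/cost_curves.csv and
# the prices list); the defaults are documented synthetic placeholders, so
# absolute cost levels are illustrative while scalings and comparisons are
# structurally faithful.

#' Default cost-curve table
#'
#' Power-law installed-cost curves and unit prices, USD(2021):
#' `cost = base_cost * (size / base_size)^exponent * install_factor`.
#' Bundled as an editable CSV of documented synthetic placeholders.
#'
#' @param path Optional path to a user-supplied CSV with the same columns.
#' @return A tibble with columns `item`, `base_cost_usd2021`, `base_size`,
#'   `unit`, `exponent`, `install_factor`, `lifetime_yr`, `note`.
#' @export
default_cost_curves <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cost_curves.csv", package = "anaerobead")
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(out$base_cost_usd2021 >= 0), all(out$exponent > 0),
            all(out$exponent <= 1.2), all(out$lifetime_yr > 0))
  out
}

#' Default price set
#'
#' @param electricity_usd_kwh Grid electricity price, USD/kWh.
#' @param natural_gas_usd_mj Natural gas price, USD/MJ.
#' @param maintenance_frac Annual maintenance as a fraction of capital.
#' @return A named list.
#' @export
default_prices <- function(electricity_usd_kwh = 0.0845,
                           natural_gas_usd_mj = 0.005,
                           maintenance_frac = 0.025) {
  list(electricity_usd_kwh = electricity_usd_kwh,
       natural_gas_usd_mj = natural_gas_usd_mj,
       maintenance_frac = maintenance_frac)
}

#' Size reactor vessels and produce the material takeoff
#'
#' Cylindrical vessels (height/diameter ratio `aspect`) in concrete with
#' rockwool insulation and a thin carbon-steel facing; the UASB adds a
#' stainless three-phase separator. Working volume is flow x HRT (beads
#' inside the working volume); a headspace fraction is added on top.
#'
#' @param config A [system_config()].
#' @param flow_m3_d Influent flow, m^3/d.
#' @param headspace_frac Headspace fraction of working volume.
#' @param aspect Vessel height-to-diameter ratio.
#' @param wall_concrete_m,wall_rockwool_m,wall_steel_m Layer thicknesses, m.
#' @return A list with `vessels` (tibble per stage: working/total volume,
#'   diameter, height) and `takeoff` (tibble item/quantity/unit).
#' @export
size_reactor <- function(config, flow_m3_d, headspace_frac = 0.15,
                         aspect = 1.5, wall_concrete_m = 0.2,
                         wall_rockwool_m = 0.1, wall_steel_m = 0.003) {
  if (flow_m3_d <= 0) stop("flow must be positive")
  splits <- if (config$stages == 2)
    c(config$hrt_split, 1 - config$hrt_split) else 1
  vessels <- purrr::map_dfr(seq_len(config$stages), function(k) {
    V <- flow_m3_d * config$hrt_d * splits[k]
    if (V <= 0) stop("nonpositive working volume")
    Vt <- V * (1 + headspace_frac)
    D <- (4 * Vt / (pi * aspect))^(1 / 3)
    H <- aspect * D
    tibble::tibble(stage = k, working_m3 = V, total_m3 = Vt,
                   diameter_m = D, height_m = H,
                   wall_m2 = pi * D * H, base_m2 = pi * D^2 / 4)
  })
  wall <- sum(vessels$wall_m2)
  base <- sum(vessels$base_m2)
  takeoff <- tibble::tibble(
    item = c("concrete", "rockwool", "carbon_steel", "hdpe"),
    quantity = c(wall * wall_concrete_m + base * 0.3,
                 wall * wall_rockwool_m,
                 wall * wall_steel_m * 7850,
                 50 + 2 * flow_m3_d),
    unit = c("m3", "m3", "kg", "kg"))
  if (config$reactor_type == "UASB") {
    takeoff <- dplyr::bind_rows(takeoff, tibble::tibble(
      item = "stainless_steel", quantity = 50 * base, unit = "kg"))
  }
  list(vessels = vessels, takeoff = takeoff)
}

#' Encapsulant inventory and replacement schedule
#'
#' @param config An encapsulated [system_config()].
#' @param working_m3 Total reactor working volume, m^3.
#' @param project_years Project lifetime, years.
#' @return A list: initial PEG mass (kg), bead volume (m^3), number of
#'   batches over the project (`ceiling(project / lifetime)`, the initial
#'   fill included) and the replacement years.
#' @export
#' @examples
#' cfg <- system_config("packed_bed", bead = bead_spec(lifetime_yr = 1))
#' encapsulant_inventory(cfg, 50)$batches  # 30 over a 30-year project
encapsulant_inventory <- function(config, working_m3, project_years = 30) {
  if (config$reactor_type == "UASB" || is.null(config$bead))
    stop("encapsulant inventory requires an encapsulated reactor with a bead spec")
  phi <- .bead_fraction(config)
  vol <- working_m3 * phi
  mass <- vol * config$bead$density_kg_m3
  batches <- as.integer(ceiling(project_years / config$bead$lifetime_yr))
  list(bead_volume_m3 = vol, peg_mass_kg = mass, batches = batches,
       replacement_years = if (batches > 1)
       config$bead$lifetime_yr * seq_len(batches - 1) else numeric())
}

#' Fluidization pumping power
#'
#' Minimum fluidization velocity from the Wen-Yu correlation
#' `Re_mf = sqrt(33.7^2 + 0.0408 Ar) - 33.7`, an operating upflow at
#' `u_op = margin x u_mf`, and pumping power from the fluidized-bed pressure
#' drop (buoyant weight of the bed).
#'
#' @param bead A [bead_spec()].
#' @param bed_area_m2 Bed cross-sectional area, m^2.
#' @param bed_height_m Expanded bed height, m.
#' @param volume_fraction Bead volume fraction.
#' @param margin Operating velocity as a multiple of u_mf.
#' @param rho_f Fluid density, kg/m^3. @param mu Dynamic viscosity, Pa s.
#' @param pump_eff Pump efficiency.
#' @return List: `u_mf_m_s`, `power_kw`, recirculation flow m^3/d.
#' @export
fluidization_power <- function(bead, bed_area_m2, bed_height_m,
                               volume_fraction, margin = 1.2,
                               rho_f = 1000, mu = 1e-3, pump_eff = 0.7) {
  d <- bead$diameter_mm / 1000
  drho <- bead$density_kg_m3 - rho_f
  if (drho <= 0) stop("bead density must exceed fluid density to fluidize")
  g <- 9.81
  Ar <- rho_f * drho * g * d^3 / mu^2
  Re_mf <- sqrt(33.7^2 + 0.0408 * Ar) - 33.7
  u_mf <- Re_mf * mu / (rho_f * d)
  u_op <- margin * u_mf
  dP <- drho * g * volume_fraction * bed_height_m        # Pa
  q <- u_op * bed_area_m2                                # m^3/s
  list(u_mf_m_s = u_mf, u_op_m_s = u_op,
       power_kw = dP * q / pump_eff / 1000,
       recirc_m3_d = q * 86400)
}

#' Packed-bed pressure gradient (Ergun equation)
#'
#' @param voidage Bed liquid fraction, in (0, 1).
#' @param diameter_mm Bead diameter, mm.
#' @param velocity_m_s Superficial velocity, m/s.
#' @param rho_f Fluid density, kg/m^3. @param mu Dynamic viscosity, Pa s.
#' @return Pressure gradient, Pa/m.
#' @export
packed_bed_pressure_drop <- function(voidage, diameter_mm, velocity_m_s,
                                     rho_f = 1000, mu = 1e-3) {
  if (voidage <= 0 || voidage >= 1) stop("voidage must be in (0, 1)")
  d <- diameter_mm / 1000
  150 * mu * (1 - voidage)^2 / (voidage^3 * d^2) * velocity_m_s +
    1.75 * rho_f * (1 - voidage) / (voidage^3 * d) * velocity_m_s^2
}

#' Influent heating duty
#'
#' `duty = rho cp Q (T_op - T_in) (1 - effectiveness)`, zero when the
#' operating temperature does not exceed the influent temperature.
#'
#' @param flow_m3_d Influent flow, m^3/d.
#' @param t_in_c,t_op_c Influent and operating temperatures, degC.
#' @param hx_effectiveness Heat-recovery effectiveness of the influent-
#'   effluent exchanger, in [0, 1).
#' @return List: `duty_kw` and `natural_gas_mj_d` (boiler at `boiler_eff`).
#' @param boiler_eff Boiler efficiency.
#' @export
heating_duty <- function(flow_m3_d, t_in_c, t_op_c, hx_effectiveness = 0.5,
                         boiler_eff = 0.9) {
  if (hx_effectiveness < 0 || hx_effectiveness >= 1)
    stop("effectiveness must be in [0, 1)")
  dT <- max(t_op_c - t_in_c, 0)
  duty_kw <- 1000 * 4.186 * flow_m3_d * dT * (1 - hx_effectiveness) / 86400
  list(duty_kw = duty_kw,
       natural_gas_mj_d = duty_kw * 86.4 / boiler_eff)
}

#' Itemized capital and O&M cost lines
#'
#' Applies the power-law cost curves to a material takeoff and equipment
#' list, and prices annual energy and encapsulant replacement.
#'
#' @param takeoff Tibble `item`, `quantity`, `unit` of materials.
#' @param equipment Tibble `item`, `size` of equipment (sized on the curve's
#'   unit), may be empty.
#' @param curves A [default_cost_curves()] table.
#' @param energy List with `electricity_kwh_d` and `natural_gas_mj_d`.
#' @param prices A [default_prices()] list.
#' @param encapsulant Optional [encapsulant_inventory()] result with
#'   `peg_price_usd_kg` taken from the curve table.
#' @param project_years Project lifetime, years.
#' @return A list with `capital` (tibble item/cost), `om_annual` (tibble
#'   item/cost per year) and totals.
#' @export
cost_lines <- function(takeoff, equipment, curves, energy, prices,
                       encapsulant = NULL, project_years = 30) {
  curve_of <- function(item) {
    row <- curves[curves$item == item, ]
    if (nrow(row) != 1) stop("no cost curve for item: ", item)
    row
  }
  cost_one <- function(item, size) {
    cv <- curve_of(item)
    cv$base_cost_usd2021 * (size / cv$base_size)^cv$exponent * cv$install_factor
  }
  cap <- tibble::tibble(item = character(), cost_usd = numeric())
  if (nrow(takeoff))
    cap <- dplyr::bind_rows(cap, tibble::tibble(
      item = takeoff$item,
      cost_usd = purrr::map2_dbl(takeoff$item, takeoff$quantity, cost_one)))
  if (!is.null(equipment) && nrow(equipment))
    cap <- dplyr::bind_rows(cap, tibble::tibble(
      item = equipment$item,
      cost_usd = purrr::map2_dbl(equipment$item, equipment$size, cost_one)))
  peg_price <- curve_of("peg_encapsulant")
  if (!is.null(encapsulant)) {
    cap <- dplyr::bind_rows(cap, tibble::tibble(
      item = "peg_encapsulant",
      cost_usd = encapsulant$peg_mass_kg * peg_price$base_cost_usd2021 *
        peg_price$install_factor))
  }
  capital_total <- sum(cap$cost_usd)
  om <- tibble::tibble(
    item = c("electricity", "heat_natural_gas", "maintenance"),
    cost_usd_yr = c(energy$electricity_kwh_d * 365 * prices$electricity_usd_kwh,
                    energy$natural_gas_mj_d * 365 * prices$natural_gas_usd_mj,
                    prices$maintenance_frac * capital_total))
  if (!is.null(encapsulant) && encapsulant$batches > 1) {
    repl <- (encapsulant$batches - 1) * encapsulant$peg_mass_kg *
      peg_price$base_cost_usd2021 * peg_price$install_factor / project_years
    om <- dplyr::bind_rows(om, tibble::tibble(
      item = "bead_replacement", cost_usd_yr = repl))
  }
  list(capital = cap, om_annual = om,
       capital_total = capital_total, om_total_yr = sum(om$cost_usd_yr))
}
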