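#' System configuration for an anaerobic treatment scenario
#'
#' Describes one flowsheet: reactor type, staging, temperature, hydraulic
#' retention time, hydrogen extraction, effluent degassing and (for
#' encapsulated reactors) the bead decisions. Invariants: beads are present
#' exactly when the reactor is encapsulated (not UASB); a bead volume
#' fraction applies only to fluidized beds and a bed voidage only to packed
#' beds; active H2 extraction (vacuum or membrane) attaches to the
#' first-stage reactor of a two-stage system only.
#'
#' @param reactor_type `"fluidized_bed"`, `"packed_bed"` or `"UASB"`.
#' @param stages 1 (single-stage) or 2 (fermenting + methanogenic).
#' @param temperature_c Operating temperature, degC (22 ambient or 35
#'   mesophilic in the discrete design space; any value allowed).
#' @param hrt_d Total hydraulic retention time, d (working volume / flow;
#'   beads counted inside the working volume).
#' @param hrt_split Fraction of total HRT given to stage 1 of a two-stage
#'   system.
#' @param h2_extraction `"passive"`, `"vacuum"` or `"membrane"`.
#' @param vacuum_bar Headspace pressure under vacuum extraction, bar.
#' @param membrane_recirc External recirculation ratio for sidestream
#'   membrane extraction.
#' @param degassing Include an effluent degassing membrane contactor?
#' @param bead A [bead_spec()], required unless UASB.
#' @param bead_volume_fraction Bead volume fraction (fluidized bed only).
#' @param bed_voidage Liquid fraction of the packed bed (packed bed only);
#'   bead fraction is `1 - bed_voidage`.
#' @param retention_factor UASB only: SRT / HRT ratio achieved by the
#'   three-phase separator (>= 1).
#' @param bed_solids_retention Packed bed only: entrapment of particulates
#'   by the bed interstices, expressed as the ratio of solids to liquid
#'   residence time (>= 1); influent solids are held until hydrolyzed.
#' @return A `system_config` list.
#' @export
#' @examples
#' system_config("fluidized_bed", hrt_d = 2, bead_volume_fraction = 0.25)
system_config <- function(reactor_type = c("fluidized_bed", "packed_bed", "UASB"),
                          stages = 1, temperature_c = 22, hrt_d = 1,
                          hrt_split = 0.25,
                          h2_extraction = c("passive", "vacuum", "membrane"),
                          vacuum_bar = 0.1, membrane_recirc = 1,
                          degassing = FALSE,
                          bead = NULL,
                          bead_volume_fraction = NULL, bed_voidage = NULL,
                          retention_factor = 15, bed_solids_retention = 10) {
  reactor_type <- match.arg(reactor_type)
  h2_extraction <- match.arg(h2_extraction)
  if (!stages %in% c(1, 2)) stop("invariant violated: stages must be 1 or 2")
  if (hrt_d <= 0) stop("invariant violated: hrt_d must be positive")
  if (stages == 2 && (hrt_split <= 0 || hrt_split >= 1))
    stop("invariant violated: hrt_split must be in (0, 1)")
  encapsulated <- reactor_type != "UASB"
  if (encapsulated && is.null(bead)) bead <- bead_spec()
  if (!encapsulated && !is.null(bead))
    stop("invariant violated: bead present requires an encapsulated reactor (not UASB)")
  if (reactor_type == "fluidized_bed") {
    if (is.null(bead_volume_fraction)) bead_volume_fraction <- 0.25
    if (bead_volume_fraction <= 0 || bead_volume_fraction >= 1)
      stop("invariant violated: bead_volume_fraction must be in (0, 1)")
  } else if (!is.null(bead_volume_fraction)) {
    stop("invariant violated: bead_volume_fraction applies to fluidized beds only")
  }
  if (reactor_type == "packed_bed") {
    if (is.null(bed_voidage)) bed_voidage <- 0.4
    if (bed_voidage <= 0 || bed_voidage >= 1)
      stop("invariant violated: bed_voidage must be in (0, 1)")
  } else if (!is.null(bed_voidage)) {
    stop("invariant violated: bed_voidage applies to packed beds only")
  }
  if (h2_extraction != "passive" && stages != 2)
    stop("invariant violated: active H2 extraction requires a two-stage system")
  if (reactor_type == "UASB" && retention_factor < 1)
    stop("invariant violated: retention_factor must be >= 1")
  if (reactor_type == "packed_bed" && bed_solids_retention < 1)
    stop("invariant violated: bed_solids_retention must be >= 1")
  structure(list(reactor_type = reactor_type, stages = as.integer(stages),
                 temperature_c = temperature_c, hrt_d = hrt_d,
                 hrt_split = hrt_split, h2_extraction = h2_extraction,
                 vacuum_bar = vacuum_bar, membrane_recirc = membrane_recirc,
                 degassing = isTRUE(degassing), bead = bead,
                 bead_volume_fraction = bead_volume_fraction,
                 bed_voidage = bed_voidage,
                 retention_factor = retention_factor,
                 bed_solids_retention = bed_solids_retention),
            class = "system_config")
}

# effluent particulate division: the UASB separator or the packed bed's
# interstitial entrapment decouple the solids from the liquid residence time
.part_div <- function(config) {
  switch(config$reactor_type,
         UASB = config$retention_factor,
         packed_bed = config$bed_solids_retention,
         fluidized_bed = 1)
}

# bead volume fraction implied by the configuration (0 for UASB)
.bead_fraction <- function(config) {
  switch(config$reactor_type,
         fluidized_bed = config$bead_volume_fraction,
         packed_bed = 1 - config$bed_voidage,
         UASB = 0)
}

#' Numerical and operational settings for system simulation
#'
#' Collects the knobs of the steady-state simulator that are not design
#' decisions: radial resolution, initial biomass, transfer coefficients and
#' integrator control.
#'
#' @param shell_count Radial shells per bead used in system simulations.
#' @param headspace_frac Headspace volume as a fraction of working volume.
#' @param kLa Gas-liquid transfer coefficient, 1/d.
#' @param k_p Headspace valve coefficient, m^3 gas d^-1 bar^-1 per m^3
#'   headspace.
#' @param x0_bead Initial encapsulated biomass density, kg-COD per m^3 bead.
#' @param x0_uasb Initial granular biomass in a UASB, kg-COD per m^3 reactor.
#' @param e_mem Single-pass H2 removal efficiency of the sidestream membrane.
#' @param degas_efficiency Dissolved-CH4 recovery efficiency of the effluent
#'   degassing contactor.
#' @param cap_sharpness Exponent of the smooth encapsulation-capacity
#'   crowding function: the fraction of gross growth sloughed to the bulk is
#'   `(biomass / capacity) ^ cap_sharpness`.
#' @param t_chunk,t_max Integration chunk length and horizon cap, d.
#' @param tol Steady-state criterion: max |dC/dt| / (|C| + eps) over the
#'   reported (bulk and gas) states, 1/d.
#' @param inoculum_role Optional override of the seeded community profile
#'   (`"balanced"`, `"fermenter"`, `"methanogen"`, `"acetoclastic"`); by
#'   default stage 1 of a two-stage system is seeded fermenter-rich, stage 2
#'   methanogen-rich, single stages balanced.
#' @param use_compiled Use the compiled right-hand side (the R reference
#'   implementation is used when `FALSE`).
#' @return A `sim_settings` list.
#' @export
sim_settings <- function(shell_count = 10, headspace_frac = 0.15,
                         kLa = 200, k_p = 5e4,
                         x0_bead = 10, x0_uasb = 20,
                         e_mem = 0.6, degas_efficiency = 0.85,
                         cap_sharpness = 12,
                         t_chunk = 200, t_max = 13000, tol = 1e-4,
                         inoculum_role = NULL,
                         use_compiled = TRUE) {
  structure(list(shell_count = as.integer(shell_count),
                 headspace_frac = headspace_frac, kLa = kLa, k_p = k_p,
                 x0_bead = x0_bead, x0_uasb = x0_uasb, e_mem = e_mem,
                 degas_efficiency = degas_efficiency,
                 cap_sharpness = cap_sharpness,
                 t_chunk = t_chunk, t_max = t_max, tol = tol,
                 inoculum_role = inoculum_role,
                 use_compiled = isTRUE(use_compiled)),
            class = "sim_settings")
}

# initial guild mass fractions by community role
.guild_profile <- function(role = c("balanced", "fermenter", "methanogen",
                                    "acetoclastic")) {
  role <- match.arg(role)
  w <- switch(role,
              balanced  = c(0.25, 0.15, 0.05, 0.10, 0.10, 0.25, 0.10),
              fermenter = c(0.40, 0.25, 0.05, 0.10, 0.10, 0.05, 0.05),
              methanogen = c(0.10, 0.05, 0.05, 0.10, 0.15, 0.35, 0.20),
              acetoclastic = c(0, 0, 0, 0, 0, 1, 0))
  stats::setNames(w, names(.cmp)[.biomass_idx])
}
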