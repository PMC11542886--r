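# Three-stage analysis machinery: discrete design-space enumeration with
# pairwise normalized indicator differences, Latin hypercube Monte Carlo
# with KS-based Monte Carlo filtering, and 2-D technology-parameter mapping
# with nested bounded optimization.

#' Default discrete decision space
#'
#' Option sets for the 11 design and operation decisions, with structural
#' applicability: bead decisions only for encapsulated reactors, bead volume
#' fraction only for fluidized beds, active H2 extraction (two vacuum
#' pressures or two membrane recirculation ratios) only for the first stage
#' of two-stage systems; single-stage systems collect biogas passively.
#'
#' @param reactor_type,stages,temperature_c,hrt_d,degassing Option vectors.
#' @param vacuum_bar,membrane_recirc Option vectors for active extraction.
#' @param bead_diameter_mm,bead_lifetime_yr Bead options (encapsulated).
#' @param bead_volume_fraction Options for fluidized beds.
#' @return A `decision_space` list of option sets.
#' @export
decision_space <- function(reactor_type = c("UASB", "packed_bed", "fluidized_bed"),
                           stages = c(1, 2), temperature_c = c(22, 35),
                           hrt_d = c(1, 2, 4, 12),
                           degassing = c(FALSE, TRUE),
                           vacuum_bar = c(0.1, 0.4),
                           membrane_recirc = c(1, 50),
                           bead_diameter_mm = c(2, 5, 10),
                           bead_lifetime_yr = c(1, 10, 30),
                           bead_volume_fraction = c(0.10, 0.25, 0.40)) {
  structure(list(reactor_type = reactor_type, stages = stages,
                 temperature_c = temperature_c, hrt_d = hrt_d,
                 degassing = degassing, vacuum_bar = vacuum_bar,
                 membrane_recirc = membrane_recirc,
                 bead_diameter_mm = bead_diameter_mm,
                 bead_lifetime_yr = bead_lifetime_yr,
                 bead_volume_fraction = bead_volume_fraction),
            class = "decision_space")
}

#' Enumerate all scenarios of a decision space
#'
#' Deterministic, duplicate-free cross product of the option sets filtered
#' by the applicability predicates, in a stable ordering. The default space
#' yields 3552 scenarios (96 UASB, 864 packed bed, 2592 fluidized bed).
#'
#' @param space A [decision_space()].
#' @return A tibble with one row per scenario.
#' @export
#' @examples
#' nrow(enumerate_scenarios(decision_space()))   # 3552
enumerate_scenarios <- function(space = decision_space()) {
  stopifnot(inherits(space, "decision_space"))
  for (nm in c("reactor_type", "stages", "temperature_c", "hrt_d",
               "degassing"))
    if (!length(space[[nm]])) stop("empty option set: ", nm)

  h2_options <- function(stg) {
    if (stg == 1)
      return(tibble::tibble(h2_extraction = "passive",
                            vacuum_bar = NA_real_,
                            membrane_recirc = NA_real_))
    if (!length(space$vacuum_bar) || !length(space$membrane_recirc))
      stop("empty option set: vacuum_bar / membrane_recirc")
    dplyr::bind_rows(
      tibble::tibble(h2_extraction = "passive", vacuum_bar = NA_real_,
                     membrane_recirc = NA_real_),
      tibble::tibble(h2_extraction = "vacuum", vacuum_bar = space$vacuum_bar,
                     membrane_recirc = NA_real_),
      tibble::tibble(h2_extraction = "membrane", vacuum_bar = NA_real_,
                     membrane_recirc = space$membrane_recirc))
  }
  one_type <- function(type) {
    base <- tidyr::expand_grid(
      reactor_type = type,
      stages = space$stages,
      temperature_c = space$temperature_c,
      hrt_d = space$hrt_d,
      degassing = space$degassing)
    base <- base |>
      dplyr::mutate(h2 = purrr::map(.data$stages, h2_options)) |>
      tidyr::unnest("h2")
    if (type == "UASB") {
      base$bead_diameter_mm <- NA_real_
      base$bead_lifetime_yr <- NA_real_
      base$bead_volume_fraction <- NA_real_
      return(base)
    }
    if (!length(space$bead_diameter_mm) || !length(space$bead_lifetime_yr))
      stop("empty option set: bead decisions")
    base <- tidyr::expand_grid(
      base, bead_diameter_mm = space$bead_diameter_mm,
      bead_lifetime_yr = space$bead_lifetime_yr)
    if (type == "fluidized_bed") {
      if (!length(space$bead_volume_fraction))
        stop("empty option set: bead_volume_fraction")
      base <- tidyr::expand_grid(
        base, bead_volume_fraction = space$bead_volume_fraction)
    } else {
      base$bead_volume_fraction <- NA_real_
    }
    base
  }
  out <- purrr::map_dfr(space$reactor_type, one_type)
  out <- dplyr::distinct(out)
  out <- dplyr::arrange(out, dplyr::across(dplyr::everything()))
  out$scenario_id <- seq_len(nrow(out))
  dplyr::relocate(out, "scenario_id")
}

#' Build a system configuration from a scenario row
#'
#' @param row One row of an [enumerate_scenarios()] tibble.
#' @param bead_defaults A [bead_spec()] supplying the non-enumerated bead
#'   parameters (diffusivity ratio, capacity, density, shells).
#' @param bed_voidage Packed-bed voidage (not part of the stage-I space).
#' @return A [system_config()].
#' @export
scenario_config <- function(row, bead_defaults = bead_spec(),
                            bed_voidage = 0.4) {
  enc <- row$reactor_type != "UASB"
  bead <- NULL
  if (enc) {
    bead <- bead_defaults
    bead$diameter_mm <- row$bead_diameter_mm
    bead$lifetime_yr <- row$bead_lifetime_yr
  }
  system_config(
    reactor_type = row$reactor_type, stages = row$stages,
    temperature_c = row$temperature_c, hrt_d = row$hrt_d,
    h2_extraction = row$h2_extraction,
    vacuum_bar = ifelse(is.na(row$vacuum_bar), 0.1, row$vacuum_bar),
    membrane_recirc = ifelse(is.na(row$membrane_recirc), 1,
                             row$membrane_recirc),
    degassing = row$degassing, bead = bead,
    bead_volume_fraction = if (row$reactor_type == "fluidized_bed")
      row$bead_volume_fraction,
    bed_voidage = if (row$reactor_type == "packed_bed") bed_voidage)
}

#' Evaluate a batch of scenarios
#'
#' Simulates each scenario to steady state and computes the indicators,
#' warm-starting each simulation from the last converged state of the same
#' reactor type and staging (the state layouts match and the fixed points
#' are close, which cuts integration time substantially).
#'
#' @param scenarios An [enumerate_scenarios()] tibble (or subset).
#' @param influent,params,settings,curves,factors,prices Shared inputs.
#' @param bead_defaults Non-enumerated bead parameters.
#' @param progress Print a line every `progress` scenarios (0 = quiet).
#' @return The scenario tibble with indicator columns appended.
#' @export
run_scenarios <- function(scenarios, influent = influent_spec(),
                          params = adm1_params(),
                          settings = sim_settings(),
                          curves = default_cost_curves(),
                          factors = default_impact_factors(),
                          prices = default_prices(),
                          bead_defaults = bead_spec(), progress = 0) {
  ord <- order(scenarios$reactor_type, scenarios$stages, scenarios$hrt_d)
  cache <- new.env(parent = emptyenv())
  res <- vector("list", nrow(scenarios))
  for (i in seq_along(ord)) {
    row <- scenarios[ord[i], ]
    cfg <- scenario_config(row, bead_defaults)
    key <- paste(row$reactor_type, row$stages)
    y0 <- if (!is.null(cache[[key]])) cache[[key]] else NULL
    out <- evaluate_scenario(cfg, influent, params, settings, curves,
                             factors, prices, y0 = y0)
    st <- attr(out, "result")
    if (st$converged) cache[[key]] <- st$state
    attr(out, "result") <- NULL
    res[[ord[i]]] <- out
    if (progress > 0 && i %% progress == 0)
      message(sprintf("scenario %d/%d", i, nrow(scenarios)))
  }
  dplyr::bind_cols(scenarios,
                   dplyr::select(dplyr::bind_rows(res),
                                 -dplyr::any_of(names(scenarios))))
}

#' Pairwise normalized indicator differences for one decision variable
#'
#' For every baseline-alternative pair of scenarios that differ only in the
#' chosen variable, the relative impact is the indicator difference
#' normalized by the indicator's range over all supplied scenarios:
#' `deltaY = (Y_alt - Y_base) / (Y_max - Y_min)`.
#'
#' @param df Scenario tibble with an indicator column.
#' @param indicator Name of the indicator column (e.g. `"lc_usd_t"`).
#' @param variable Decision-variable column name.
#' @param baseline Baseline level of the variable.
#' @return Tibble: one row per pair with `alternative`, `delta`, and the
#'   baseline/alternative indicator values.
#' @export
pairwise_delta <- function(df, indicator, variable, baseline) {
  y <- df[[indicator]]
  if (length(unique(y)) < 2) stop("need at least 2 distinct indicator values")
  rng <- max(y) - min(y)
  if (rng == 0) stop("degenerate normalization: indicator range is zero")
  dec_cols <- intersect(
    c("reactor_type", "stages", "temperature_c", "hrt_d", "h2_extraction",
      "vacuum_bar", "membrane_recirc", "degassing", "bead_diameter_mm",
      "bead_lifetime_yr", "bead_volume_fraction"), names(df))
  other <- setdiff(dec_cols, variable)
  df$..y <- y
  df$..v <- df[[variable]]
  base <- df[!is.na(df$..v) & df$..v == baseline, ]
  alts <- df[!is.na(df$..v) & df$..v != baseline, ]
  if (!nrow(base) || !nrow(alts))
    return(tibble::tibble(variable = character(), alternative = character(),
                          y_base = numeric(), y_alt = numeric(),
                          delta = numeric()))
  key <- function(d) do.call(paste, c(lapply(other, function(cc) d[[cc]]),
                                      sep = "\r"))
  base$..k <- key(base); alts$..k <- key(alts)
  j <- dplyr::inner_join(
    dplyr::select(base, "..k", y_base = "..y"),
    dplyr::select(alts, "..k", y_alt = "..y", alternative = "..v"),
    by = "..k", relationship = "many-to-many")
  tibble::tibble(variable = variable,
                 alternative = as.character(j$alternative),
                 y_base = j$y_base, y_alt = j$y_alt,
                 delta = (j$y_alt - j$y_base) / rng)
}

#' Latin hypercube sample of a parameter distribution set
#'
#' One sample per equal-probability stratum per parameter, transformed
#' through each parameter's inverse CDF. Deterministic under a fixed seed;
#' a single matrix is meant to be shared across reactor types for paired
#' comparisons.
#'
#' @param dist_set Tibble with columns `name`, `dist`
#'   (`"uniform"`, `"loguniform"` or `"triangle"`), `min`, `max` and
#'   optional `mode` (triangle).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return A tibble with `n` rows and one column per parameter.
#' @export
lhs_sample <- function(dist_set, n, seed = 1) {
  stopifnot(n >= 1, all(is.finite(dist_set$min)), all(is.finite(dist_set$max)))
  k <- nrow(dist_set)
  set.seed(seed)
  u <- lhs::randomLHS(n, k)
  qtriangle <- function(p, a, b, m) {
    fc <- (m - a) / (b - a)
    ifelse(p < fc, a + sqrt(p * (b - a) * (m - a)),
           b - sqrt((1 - p) * (b - a) * (b - m)))
  }
  out <- purrr::map_dfc(seq_len(k), function(j) {
    d <- dist_set[j, ]
    x <- switch(as.character(d$dist),
                uniform = d$min + u[, j] * (d$max - d$min),
                loguniform = exp(log(d$min) + u[, j] * (log(d$max) - log(d$min))),
                triangle = qtriangle(u[, j], d$min, d$max,
                                     if (!is.null(d$mode) && !is.na(d$mode))
                                       d$mode else (d$min + d$max) / 2),
                stop("unknown distribution family: ", d$dist))
    tibble::tibble(!!d$name := x)
  })
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum absolute difference between the two empirical CDFs;
#' the p-value uses the asymptotic two-sample Kolmogorov distribution.
#'
#' @param a,b Numeric sample vectors (length >= 2 each).
#' @return Tibble: `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  tibble::tibble(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 n_a = length(a), n_b = length(b))
}

#' Monte Carlo filtering with KS tests
#'
#' Splits the Monte Carlo sample into a desirable group (top 25% of the
#' indicator when higher is better, bottom 25% when lower is better) and the
#' complementary 75%, then tests each parameter's distributional shift
#' between groups with a two-sample KS test.
#'
#' @param samples Tibble of parameter samples (one column per parameter).
#' @param y Indicator values, one per sample row.
#' @param direction `"higher_better"` (e.g. rCOD) or `"lower_better"`
#'   (e.g. LC, CI).
#' @return Tibble: `parameter`, `statistic`, `p_value`, group sizes.
#' @export
monte_carlo_filter <- function(samples, y,
                               direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  stopifnot(nrow(samples) == length(y), all(is.finite(y)))
  q <- if (direction == "higher_better") stats::quantile(y, 0.75)
       else stats::quantile(y, 0.25)
  desirable <- if (direction == "higher_better") y > q else y < q
  if (sum(desirable) < 2 || sum(!desirable) < 2)
    stop("degenerate split: a group has fewer than 2 samples")
  purrr::map_dfr(names(samples), function(p) {
    ks <- ks_two_sample(samples[[p]][desirable], samples[[p]][!desirable])
    tibble::tibble(parameter = p, statistic = ks$statistic,
                   p_value = ks$p_value,
                   n_desirable = ks$n_a, n_undesirable = ks$n_b)
  })
}

#' KS filtering on reactor preference
#'
#' Groups the shared sample matrix by which reactor type performs better on
#' a paired indicator (evaluated on identical samples) and KS-tests each
#' parameter between the two preference groups.
#'
#' @param samples Shared parameter sample tibble.
#' @param y_a,y_b Paired indicator values for the two reactor types.
#' @param direction Is a smaller indicator better?
#' @return Tibble as in [monte_carlo_filter()], with `n_a_better` sizes.
#' @export
reactor_preference_filter <- function(samples, y_a, y_b,
                                      direction = c("lower_better",
                                                    "higher_better")) {
  direction <- match.arg(direction)
  stopifnot(nrow(samples) == length(y_a), length(y_a) == length(y_b))
  a_better <- if (direction == "lower_better") y_a < y_b else y_a > y_b
  if (sum(a_better) < 2 || sum(!a_better) < 2)
    stop("degenerate preference split: one group has fewer than 2 samples (",
         sum(a_better), " vs ", sum(!a_better), ")")
  purrr::map_dfr(names(samples), function(p) {
    ks <- ks_two_sample(samples[[p]][a_better], samples[[p]][!a_better])
    tibble::tibble(parameter = p, statistic = ks$statistic,
                   p_value = ks$p_value,
                   n_a_better = ks$n_a, n_b_better = ks$n_b)
  })
}

#' Map optimized performance over a 2-D technology-parameter grid
#'
#' For every point of the grid spanned by two uncertain technology
#' parameters, runs a seeded multi-start bounded optimization of the
#' decision variables to minimize the objective (carbon intensity of COD
#' removal), and records the tailored decision variables with the resulting
#' indicators. The default grid resolution (12 x 15) evaluates 180 points.
#'
#' @param eval_fn Function `(par, dv)` where `par` is a named list with the
#'   two grid-parameter values and `dv` a named vector of decision
#'   variables; must return a list with at least `ci` (the objective),
#'   optionally `lc` and `rcod`.
#' @param param1,param2 Lists `list(name = , values = )` defining the grid.
#' @param dv_bounds Named list of `c(lower, upper)` per decision variable.
#' @param n_starts Number of optimizer starts per grid point.
#' @param seed Integer seed for the start draws.
#' @param maxit L-BFGS-B iteration cap per start.
#' @return A `stage3_map` tibble: grid values, optimized DVs, `ci`, `lc`,
#'   `rcod`, `converged`, `n_evals`.
#' @export
stage3_map <- function(eval_fn, param1, param2, dv_bounds,
                       n_starts = 8, seed = 1, maxit = 40) {
  stopifnot(length(param1$values) >= 1, length(param2$values) >= 1,
            length(dv_bounds) >= 1)
  dv_names <- names(dv_bounds)
  lo <- vapply(dv_bounds, `[`, 0, 1)
  hi <- vapply(dv_bounds, `[`, 0, 2)
  stopifnot(all(hi > lo))
  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * length(dv_names)),
                   n_starts, length(dv_names))
  starts[1, ] <- 0.5
  grid <- tidyr::expand_grid(p1 = param1$values, p2 = param2$values)
  prev_best <- NULL
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    par <- stats::setNames(list(grid$p1[g], grid$p2[g]),
                           c(param1$name, param2$name))
    n_evals <- 0L
    best <- NULL
    obj <- function(z) {
      dv <- stats::setNames(lo + z * (hi - lo), dv_names)
      r <- eval_fn(par, dv)
      n_evals <<- n_evals + 1L
      if (is.null(best) || r$ci < best$ci)
        best <<- c(list(dv = dv), r)
      r$ci
    }
    st_list <- lapply(seq_len(n_starts), function(s) starts[s, ])
    if (!is.null(prev_best))
      st_list <- c(list((prev_best - lo) / (hi - lo)), st_list)
    ok <- FALSE
    for (z0 in st_list) {
      fit <- tryCatch(
        stats::optim(z0, obj, method = "L-BFGS-B", lower = 0, upper = 1,
                     control = list(maxit = maxit, factr = 1e10)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$convergence == 0) ok <- TRUE
    }
    prev_best <- best$dv
    row <- tibble::tibble(!!param1$name := grid$p1[g],
                          !!param2$name := grid$p2[g],
                          ci = best$ci,
                          lc = if (!is.null(best$lc)) best$lc else NA_real_,
                          rcod = if (!is.null(best$rcod)) best$rcod
                                 else NA_real_,
                          converged = ok, n_evals = n_evals)
    for (nm in dv_names) row[[paste0("dv_", nm)]] <- best$dv[[nm]]
    out[[g]] <- row
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("stage3_map", class(res))
  res
}

#' Rank correlation between two indicators
#'
#' Spearman rank correlation, used to justify optimizing a single objective
#' when cost and carbon intensity are strongly coupled.
#'
#' @param x,y Indicator vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
indicator_rank_correlation <- function(x, y) {
  stats::cor(x, y, method = "spearman")
}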