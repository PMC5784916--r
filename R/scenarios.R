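#' Scenario configuration
#'
#' Switches and settings for one simulation: which forcings are active
#' (oil mortality, oil growth effects, fishery closures, larval recruitment
#' losses), the sensitivity reductions applied to the concentration factor K
#' and the mortality threshold beta (each in {0, 20, 40, 60} percent, giving
#' K in {1000, 800, 600, 400} and beta in {907, 726, 544, 363}), the
#' spin-up length, the oil forcing duration and the projection horizon.
#' Simulation day 1 is 1 January of the spill year; the spill begins on day
#' 110 (20 April), after the 100-day spin-up.
#'
#' @param oil_mortality,oil_growth,closures,recruitment forcing toggles.
#' @param K_reduction,beta_reduction percent reductions from {0, 20, 40, 60}.
#' @param spin_up_days unforced days before the spill (default 100).
#' @param forcing_days oil forcing duration in days (default 167).
#' @param horizon_years total simulated years (default 10 at demo scale).
#' @param seed integer seed forwarded to input generators.
#' @param label optional scenario label; default follows the
#'   `K1000 b363` convention.
#' @return a `scenario_config`.
#' @export
scenario_config <- function(oil_mortality = TRUE, oil_growth = TRUE,
                            closures = FALSE, recruitment = FALSE,
                            K_reduction = 0, beta_reduction = 0,
                            spin_up_days = 100, forcing_days = 167,
                            horizon_years = 10, seed = 1, label = NULL) {
  ok <- c(0, 20, 40, 60)
  if (!(K_reduction %in% ok) || !(beta_reduction %in% ok))
    stop("K_reduction and beta_reduction must be one of 0, 20, 40, 60")
  if (horizon_years < 1) stop("horizon_years must be >= 1")
  base <- dose_response_params()
  K <- base$K * (1 - K_reduction / 100)
  beta <- base$beta * (1 - beta_reduction / 100)
  if (is.null(label))
    label <- sprintf("K%d b%d", round(K), round(beta))
  structure(list(oil_mortality = oil_mortality, oil_growth = oil_growth,
                 closures = closures, recruitment = recruitment,
                 K_reduction = K_reduction, beta_reduction = beta_reduction,
                 K = K, beta = beta, spin_up_days = spin_up_days,
                 forcing_days = forcing_days, horizon_years = horizon_years,
                 spill_day = spin_up_days + 10, seed = seed, label = label),
            class = "scenario_config")
}

#' Build the packaged demo inputs
#'
#' Generates the reduced study system used throughout: a 16-polygon shelf-
#' to-basin geometry with the standard depth partition (up to 6 water layers
#' plus sediment), the 12-group food web, the synthetic spill (87 days of
#' release tracked for 167 days from day 110), the 365-day emergency closure
#' schedule, larval loss fractions,
#' and a burned-in, re-balanced ecosystem state sitting on its attractor.
#' Deterministic given `seed`. The burn-in (about 18 simulated years with
#' periodic re-anchoring) takes roughly a minute; results are cached per
#' seed within the session.
#'
#' @param seed integer master seed.
#' @param horizon_years default projection horizon carried into configs.
#' @param cache use the in-session cache (default TRUE).
#' @return list with `geometry`, `web`, `oil`, `oil_polygons`, `closures`,
#'   `larval`, `params`, `state0`.
#' @export
demo_inputs <- function(seed = 1, horizon_years = 10, cache = TRUE) {
  key <- paste0("demo_", seed)
  if (cache && !is.null(.spillweb_cache[[key]]))
    return(.spillweb_cache[[key]])
  # The study system itself (geometry, food web, calibrated state) is one
  # fixed, validated configuration, like a single calibrated regional model;
  # the seed drives the quantities the study treats as stochastic: larval
  # losses and the transport wiggle of the oil field.
  geometry <- gen_geometry(n_polygons = 16, seed = 2L)
  web <- gen_food_web(seed = 1L)
  field <- gen_oil_field(geometry, seed = seed + 3000L)
  oilp <- aggregate_to_polygons(field, geometry)
  closures <- gen_closures(geometry, start_day = 110, seed = seed + 4000L)
  larval <- gen_larval_loss(web, seed = seed + 5000L)
  params <- dose_response_params()
  state0 <- init_state(web, geometry, seed = 1L)
  for (yrs in c(4, 2, 2, 4)) {
    state0 <- run_unforced(state0, web, 365 * yrs)
    state0 <- rebalance_state(state0, web)
  }
  state0 <- run_unforced(state0, web, 365 * 6)
  out <- list(geometry = geometry, web = web, oil_field = field,
              oil_polygons = oilp, closures = closures, larval = larval,
              params = params, state0 = state0, seed = seed)
  if (cache) .spillweb_cache[[key]] <- out
  out
}

.spillweb_cache <- new.env(parent = emptyenv())

#' Resolve a scenario against a set of inputs
#'
#' Scales the dose-response parameters by the configured K and beta
#' reductions, precomputes the daily toxicology forcing (body burdens and
#' modifiers) over the whole horizon, and attaches the closure schedule and
#' larval-loss table according to the toggles.
#'
#' @param config a [scenario_config()].
#' @param inputs as returned by [demo_inputs()].
#' @return a `scenario` ready for [run_scenario()].
#' @export
build_scenario <- function(config, inputs) {
  if (!inherits(config, "scenario_config")) stop("config must be a scenario_config")
  n_days <- config$horizon_years * 365
  params <- inputs$params
  params$K <- config$K
  params$beta <- config$beta
  tox <- NULL
  if (config$oil_mortality || config$oil_growth) {
    tox <- polygon_modifier_series(inputs$oil_polygons, inputs$geometry,
                                   inputs$web, params,
                                   n_days = min(n_days, config$spill_day +
                                                  config$forcing_days + 200),
                                   start_day = config$spill_day)
  }
  structure(list(config = config, inputs = inputs, params = params,
                 tox = tox,
                 closures = if (config$closures) inputs$closures else NULL,
                 larval = if (config$recruitment) inputs$larval else NULL),
            class = "scenario")
}

#' Run one scenario
#'
#' Integrates the ecosystem at 12-hour steps over the configured horizon:
#' spin-up with no forcings, the oil forcing window (with depuration
#' continuing afterwards until body burdens clear), closures and spill-year
#' larval losses as toggled. Records monthly state snapshots (numbers,
#' reserve and structural nitrogen per group, age and polygon), monthly
#' biomass, monthly guild-level consumption matrices, monthly flux
#' aggregates and annual catch by fleet. Fully deterministic.
#'
#' @param scenario from [build_scenario()].
#' @param verbose print one line per simulated year.
#' @return a `run_output`.
#' @export
run_scenario <- function(scenario, verbose = FALSE) {
  cfg <- scenario$config
  inputs <- scenario$inputs
  web <- inputs$web
  state <- inputs$state0
  state$day <- 0L
  state$event_day <- 0L
  cal <- state$calib
  nc <- cal$nc
  np <- state$n_polygons
  ng <- nrow(web$groups)
  n_days <- cfg$horizon_years * 365
  month_len <- 365 / 12
  n_months <- cfg$horizon_years * 12
  spill_year <- ceiling(cfg$spill_day / 365)

  B_month <- array(0, c(n_months, ng, np))
  N_month <- array(0, c(n_months, nc, np))
  rN_month <- array(0, c(n_months, nc))
  sN_month <- array(0, c(n_months, nc))
  cons_month <- array(0, c(n_months, ng, ng))
  predN_month <- matrix(0, n_months, ng)
  catch_year <- matrix(0, cfg$horizon_years, length(cal$fleets),
                       dimnames = list(NULL, cal$fleets))
  flux_month <- list(pred = array(0, c(n_months, ng, np)),
                     m1 = array(0, c(n_months, ng, np)),
                     growth = array(0, c(n_months, ng, np)),
                     recruit = array(0, c(n_months, ng, np)))
  gi <- cal$cells$gi
  cons_acc <- matrix(0, nc, nc)
  tox_nd <- if (!is.null(scenario$tox)) scenario$tox$n_days else 0
  month_ends <- round(seq_len(n_months) * month_len)
  month_of_day <- match(seq_len(n_days), month_ends)

  for (day in seq_len(n_days)) {
    yr <- ceiling(day / 365)
    mo <- NULL; gm <- NULL
    if (!is.null(scenario$tox) && day <= tox_nd) {
      if (cfg$oil_mortality) mo <- scenario$tox$m_oil[day, , ]
      if (cfg$oil_growth) gm <- scenario$tox$g_mult[day, , ]
    }
    cl <- if (!is.null(scenario$closures))
      closed_fraction(scenario$closures, day, np, cal$fleets) else NULL
    lv <- if (!is.null(scenario$larval) && yr == spill_year)
      scenario$larval else NULL
    for (half in 1:2) {
      r <- step(state, web, m_oil = mo, g_mult = gm, closed = cl,
                larval_loss = lv, dt = 0.5)
      state <- r$state
      fx <- r$fluxes
      catch_year[yr, ] <- catch_year[yr, ] + fx$catch_by_fleet
      cons_acc <- cons_acc + fx$consumption
      mi <- min(floor((day - 1) / month_len) + 1, n_months)
      flux_month$pred[mi, , ] <- flux_month$pred[mi, , ] + rowsum(fx$pred_loss, gi)
      flux_month$m1[mi, , ] <- flux_month$m1[mi, , ] + rowsum(fx$m1_loss, gi)
      flux_month$growth[mi, , ] <- flux_month$growth[mi, , ] + rowsum(fx$growth, gi)
      flux_month$recruit[mi, , ] <- flux_month$recruit[mi, , ] +
        rowsum(fx$recruit_in, gi)
    }
    # month-end snapshot
    mi <- month_of_day[day]
    if (!is.na(mi)) {
      w <- state$sN + state$rN
      B_month[mi, , ] <- rowsum(state$N * w, gi)
      N_month[mi, , ] <- state$N
      rN_month[mi, ] <- rowSums(state$N * state$rN) / pmax(rowSums(state$N), 1e-300)
      sN_month[mi, ] <- rowSums(state$N * state$sN) / pmax(rowSums(state$N), 1e-300)
      cons_month[mi, , ] <- rowsum(t(rowsum(t(cons_acc), gi)), gi)
      predN_month[mi, ] <- rowsum(rowSums(state$N), gi)[, 1]
      cons_acc <- matrix(0, nc, nc)
    }
    if (verbose && day %% 365 == 0)
      message(sprintf("[%s] year %d / %d", cfg$label, yr, cfg$horizon_years))
  }
  structure(list(label = cfg$label, config = cfg,
                 months = seq_len(n_months),
                 biomass = B_month, numbers = N_month,
                 rN = rN_month, sN = sN_month,
                 consumption = cons_month, pred_numbers = predN_month,
                 catch = catch_year, flux = flux_month,
                 cells = cal$cells, groups = web$groups,
                 spill_day = cfg$spill_day,
                 final_state = state),
            class = "run_output")
}

#' Run the K x beta sensitivity grid
#'
#' The full cross of K reductions {0, 20, 40, 60} by beta reductions
#' {0, 20, 40, 60}: 16 oil simulations plus one shared no-oil baseline.
#'
#' @param base_config template [scenario_config()] (toggles other than oil
#'   are inherited).
#' @param inputs as from [demo_inputs()].
#' @param K_reductions,beta_reductions subsets of {0, 20, 40, 60}.
#' @param verbose forwarded to [run_scenario()].
#' @return list with `baseline` (a `run_output`) and `runs` (named list of
#'   16 `run_output`s with `K1000 b907` ... `K400 b363` labels).
#' @export
run_sensitivity_grid <- function(base_config = scenario_config(),
                                 inputs = demo_inputs(),
                                 K_reductions = c(0, 20, 40, 60),
                                 beta_reductions = c(0, 20, 40, 60),
                                 verbose = FALSE) {
  bc <- base_config
  baseline_cfg <- scenario_config(oil_mortality = FALSE, oil_growth = FALSE,
                                  closures = FALSE, recruitment = FALSE,
                                  spin_up_days = bc$spin_up_days,
                                  forcing_days = bc$forcing_days,
                                  horizon_years = bc$horizon_years,
                                  seed = bc$seed, label = "baseline")
  baseline <- run_scenario(build_scenario(baseline_cfg, inputs), verbose)
  runs <- list()
  for (rk in K_reductions) for (rb in beta_reductions) {
    cfg <- scenario_config(oil_mortality = TRUE, oil_growth = TRUE,
                           closures = bc$closures, recruitment = bc$recruitment,
                           K_reduction = rk, beta_reduction = rb,
                           spin_up_days = bc$spin_up_days,
                           forcing_days = bc$forcing_days,
                           horizon_years = bc$horizon_years, seed = bc$seed)
    runs[[cfg$label]] <- run_scenario(build_scenario(cfg, inputs), verbose)
  }
  list(baseline = baseline, runs = runs)
}

#' Single-factor runs: closures only and recruitment only
#'
#' Two simulations with exactly one non-oil forcing each, paired to the
#' shared baseline, quantifying the fishery-closure and larval-mortality
#' effects in isolation.
#'
#' @inheritParams run_sensitivity_grid
#' @return list with `baseline`, `closures_only`, `recruitment_only`.
#' @export
single_factor_runs <- function(base_config = scenario_config(),
                               inputs = demo_inputs(), verbose = FALSE) {
  bc <- base_config
  mk <- function(cl, rec, label)
    scenario_config(oil_mortality = FALSE, oil_growth = FALSE,
                    closures = cl, recruitment = rec,
                    spin_up_days = bc$spin_up_days,
                    forcing_days = bc$forcing_days,
                    horizon_years = bc$horizon_years, seed = bc$seed,
                    label = label)
  list(baseline = run_scenario(build_scenario(
         mk(FALSE, FALSE, "baseline"), inputs), verbose),
       closures_only = run_scenario(build_scenario(
         mk(TRUE, FALSE, "closures-only"), inputs), verbose),
       recruitment_only = run_scenario(build_scenario(
         mk(FALSE, TRUE, "recruitment-only"), inputs), verbose))
}
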