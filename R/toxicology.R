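#' Dose-response and bioaccumulation parameters
#'
#' Bundles the toxicological constants used to convert PAH exposure into
#' per-day mortality and growth modifiers: hockey-stick slopes and thresholds,
#' the mean exposure time used to express effects per day, the
#' sediment-to-water concentration factor, uptake constants for the benthic
#' and pelagic pathways, and the depuration rate.
#'
#' Defaults are the maximum-likelihood estimates used for fish exposed to
#' petrogenic PAHs: `alpha = 0.2885`, `beta = 907.4306` ppb, `gamma = 0.0531`,
#' `delta = 28.422` ppb, `omega = 15` days, `K = 1000`, `mu_benthic = 1`,
#' `mu_pelagic = 0.1`, and `rho = 0.2424` per day (99% clearance in 20 days).
#'
#' @param alpha mortality slope (dimensionless).
#' @param beta PAH threshold (ppb) above which mortality effects manifest.
#' @param gamma growth slope (dimensionless).
#' @param delta PAH threshold (ppb) above which growth effects manifest.
#' @param omega mean exposure time (days) used to express effects per day.
#' @param K sediment-to-water-column concentration factor (dimensionless).
#' @param mu_benthic uptake constant for sediment-associated exposure.
#' @param mu_pelagic uptake constant for water-column exposure.
#' @param rho depuration rate (per day).
#' @param K_applies_pelagic should `K` also scale the pelagic body burden
#'   inside the dose-response (the printed form of the model), or only the
#'   benthic pathway? Default `TRUE` (as printed).
#' @return An object of class `dose_response_params`.
#' @export
dose_response_params <- function(alpha = 0.2885, beta = 907.4306,
                                 gamma = 0.0531, delta = 28.422,
                                 omega = 15, K = 1000,
                                 mu_benthic = 1, mu_pelagic = 0.1,
                                 rho = 0.2424, K_applies_pelagic = TRUE) {
  p <- list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
            omega = omega, K = K, mu_benthic = mu_benthic,
            mu_pelagic = mu_pelagic, rho = rho,
            K_applies_pelagic = isTRUE(K_applies_pelagic))
  num <- vapply(p[c("alpha", "beta", "gamma", "delta", "omega", "K",
                    "mu_benthic", "mu_pelagic", "rho")], identity, 0)
  if (any(!is.finite(num)) || any(num < 0))
    stop("all dose-response parameters must be finite and non-negative")
  if (omega <= 0) stop("omega must be > 0")
  class(p) <- "dose_response_params"
  p
}

#' Hockey-stick mortality dose-response
#'
#' Added per-day mortality as a function of accumulated body burden `phi`:
#' zero at or below the threshold, log-linear above it,
#' `alpha * log(K * phi / beta) / omega`.
#'
#' @param phi accumulated bioavailable oil (ppb-equivalent); vectorised.
#' @param params a [dose_response_params()] object.
#' @param K concentration factor applied to `phi`; defaults to `params$K`.
#' @return per-day mortality modifier, same shape as `phi`.
#' @export
mortality_effect <- function(phi, params, K = params$K) {
  if (any(phi < 0, na.rm = TRUE)) stop("phi must be non-negative")
  x <- K * phi
  out <- numeric(length(phi))
  up <- is.finite(x) & x > params$beta
  out[up] <- params$alpha * log(x[up] / params$beta) / params$omega
  dim(out) <- dim(phi)
  out
}

#' Hockey-stick growth dose-response
#'
#' Growth effect size and the corresponding multiplicative modifier on growth
#' rate. The effect is zero at or below the threshold `delta` and
#' `gamma * log(K * phi / delta) / omega` above it; the multiplier is
#' `max(0, 1 - effect)` so growth is never driven negative by oil alone.
#'
#' @inheritParams mortality_effect
#' @return a list with components `effect` (per day) and `multiplier`
#'   (in `[0, 1]`), each the same shape as `phi`.
#' @export
growth_effect <- function(phi, params, K = params$K) {
  if (any(phi < 0, na.rm = TRUE)) stop("phi must be non-negative")
  x <- K * phi
  eff <- numeric(length(phi))
  up <- is.finite(x) & x > params$delta
  eff[up] <- params$gamma * log(x[up] / params$delta) / params$omega
  mult <- pmax(0, 1 - eff)
  dim(eff) <- dim(phi)
  dim(mult) <- dim(phi)
  list(effect = eff, multiplier = mult)
}

#' One step of the uptake-depuration body-burden recursion
#'
#' `phi_t = phi_{t-1} * exp(-rho) + mu * O_t`: yesterday's burden depurates by
#' the first-order rate `rho`, then today's pollutant load `O_t` is taken up
#' with efficiency `mu`. With `rho = 0.2424` an unforced burden clears 99% in
#' 20 days; under constant forcing `O = c` the burden converges to
#' `mu * c / (1 - exp(-rho))`.
#'
#' @param phi_prev burden at the previous day (ppb-equivalent); vectorised.
#' @param O_t pollutant concentration today (ppb); vectorised.
#' @param mu uptake constant.
#' @param rho depuration rate (per day).
#' @return updated burden, same shape as the inputs.
#' @export
update_body_burden <- function(phi_prev, O_t, mu, rho) {
  if (any(phi_prev < 0) || any(O_t < 0) || mu < 0 || rho < 0)
    stop("body-burden inputs must be non-negative")
  phi_prev * exp(-rho) + mu * O_t
}

# Run the burden recursion down the rows of a (day x unit) matrix.
body_burden_series <- function(O, mu, rho, phi0 = 0) {
  O <- as.matrix(O)
  phi <- matrix(0, nrow(O), ncol(O), dimnames = dimnames(O))
  prev <- rep(phi0, length.out = ncol(O))
  dec <- exp(-rho)
  for (d in seq_len(nrow(O))) {
    prev <- prev * dec + mu * O[d, ]
    phi[d, ] <- prev
  }
  phi
}

#' Proportion of a diet drawn from benthic prey
#'
#' Sediment-association proxy: the share of a predator's realised diet that
#' comes from benthic-flagged prey, used to weight the benthic versus pelagic
#' exposure pathways. An all-zero diet row returns 0.
#'
#' @param diet_row availability/diet fractions over prey (substochastic).
#' @param benthic_flags logical vector, `TRUE` for benthic prey.
#' @return a value in `[0, 1]`.
#' @export
benthic_diet_fraction <- function(diet_row, benthic_flags) {
  if (length(diet_row) != length(benthic_flags))
    stop("diet_row and benthic_flags must have equal length")
  if (any(diet_row < 0)) stop("diet fractions must be non-negative")
  tot <- sum(diet_row)
  if (tot <= 0) return(0)
  sum(diet_row[benthic_flags]) / tot
}

#' Combine pelagic and benthic effect modifiers
#'
#' Convex combination `pelagic * (1 - frac) + benthic * frac`, where `frac` is
#' the proportion of the group's diet from benthic prey. Used identically for
#' mortality and growth effects.
#'
#' @param pelagic_effect,benthic_effect non-negative effect sizes (vectorised).
#' @param benthic_frac weight in `[0, 1]`.
#' @return combined effect, always between the two inputs.
#' @export
combine_modifiers <- function(pelagic_effect, benthic_effect, benthic_frac) {
  if (any(benthic_frac < 0 | benthic_frac > 1))
    stop("benthic_frac must lie in [0, 1]")
  pelagic_effect * (1 - benthic_frac) + benthic_effect * benthic_frac
}

#' Aggregate a gridded oil field onto model polygons
#'
#' Area-weighted mean PAH concentration per polygon, water layer and day,
#' the per-day fraction of each polygon's grid cells that contain oil in any
#' layer, and the depth-averaged water-column concentration per polygon (the
#' quantity the concentration factor `K` scales into a sediment exposure).
#'
#' @param field an `oil_field` from [gen_oil_field()].
#' @param geometry a `spill_geometry` from [gen_geometry()].
#' @param oiled_threshold concentration (ppb) above which a cell counts as
#'   containing oil; keeps far-field kernel tails from flagging whole
#'   polygons as oiled.
#' @return A `polygon_oil_series`: list with `water_conc`
#'   (day x polygon x layer), `oiled_cell_fraction` (day x polygon),
#'   `bottom_conc` (day x polygon, depth-averaged over occupied layers),
#'   and `days`.
#' @export
aggregate_to_polygons <- function(field, geometry, oiled_threshold = 1e-3) {
  if (!inherits(field, "oil_field")) stop("field must be an oil_field")
  if (!inherits(geometry, "spill_geometry")) stop("geometry must be a spill_geometry")
  if (field$nx != geometry$nx || field$ny != geometry$ny)
    stop("oil field grid does not match geometry grid")
  nd <- field$track_days
  nl <- field$n_layers
  np <- geometry$n_polygons
  ncell <- geometry$nx * geometry$ny
  # membership weight matrix: cell x polygon, columns sum to 1
  W <- matrix(0, ncell, np)
  W[cbind(geometry$cells$cell, geometry$cells$polygon)] <- geometry$cells$weight
  conc <- field$conc  # array day x layer x cell
  water <- array(0, c(nd, np, nl))
  flat <- matrix(conc, nd * nl, ncell)
  agg <- flat %*% W
  water[] <- aperm(array(agg, c(nd, nl, np)), c(1, 3, 2))
  # oiled fraction: share of member cells with oil in any layer
  anyoil <- matrix(0, nd, ncell)
  for (l in seq_len(nl)) anyoil <- pmax(anyoil, matrix(conc[, l, ], nd, ncell))
  frac <- (anyoil > oiled_threshold) %*% W
  # depth-averaged water-column concentration per polygon (occupied layers)
  thick <- geometry$layer_thickness  # polygon x layer (0 where unoccupied)
  tw <- thick / pmax(rowSums(thick), 1e-12)
  bottom <- matrix(0, nd, np)
  for (p in seq_len(np))
    bottom[, p] <- water[, p, , drop = FALSE][, 1, ] %*% tw[p, ]
  structure(list(water_conc = water, oiled_cell_fraction = frac,
                 bottom_conc = bottom, days = seq_len(nd),
                 n_layers = nl, n_polygons = np),
            class = "polygon_oil_series")
}

#' Daily mortality and growth modifiers per group and polygon
#'
#' The full daily toxicology pipeline. Water-column concentrations drive a
#' pelagic body burden per polygon and layer (uptake `mu_pelagic`);
#' depth-averaged concentrations drive a benthic burden per polygon (uptake
#' `mu_benthic`). Burdens are driven by the mean concentration over the
#' *oiled* cells of a polygon, effects are evaluated on the hockey sticks and
#' then down-weighted by the oiled-cell fraction, so unoiled cells contribute
#' zero effect. Pelagic effects are averaged over each group's vertical
#' distribution; pelagic and benthic effects are then combined by the group's
#' benthic diet fraction. Only fish receive modifiers. After the forcing
#' window concentrations are zero and burdens depurate, so effects decay
#' toward zero.
#'
#' @param oil a `polygon_oil_series` from [aggregate_to_polygons()].
#' @param geometry the matching `spill_geometry`.
#' @param web a `food_web` from [gen_food_web()].
#' @param params a [dose_response_params()] object.
#' @param n_days total number of days of forcing to produce (at least the
#'   length of the oil series; later days carry depuration only).
#' @param start_day simulation day on which oil-series day 1 falls.
#' @return A `tox_forcing`: list of arrays `m_oil`, `g_mult` (day x polygon x
#'   group, days indexed from simulation day 1), component effect arrays, the
#'   body-burden arrays, and `benthic_frac` per group.
#' @export
polygon_modifier_series <- function(oil, geometry, web, params,
                                    n_days = NULL, start_day = 1) {
  if (!inherits(oil, "polygon_oil_series")) stop("oil must be a polygon_oil_series")
  if (!all(diff(oil$days) == 1)) stop("oil series days must be contiguous")
  np <- oil$n_polygons
  nl <- oil$n_layers
  ng <- nrow(web$groups)
  nfd <- length(oil$days)
  if (is.null(n_days)) n_days <- start_day - 1 + nfd + 120
  # pad forcing into the full simulation-day axis
  pad <- function(x) {
    out <- array(0, c(n_days, dim(x)[-1]))
    d0 <- start_day - 1
    keep <- seq_len(min(nfd, n_days - d0))
    idx <- d0 + keep
    if (length(dim(x)) == 2) out[idx, ] <- x[keep, , drop = FALSE]
    else out[idx, , ] <- x[keep, , , drop = FALSE]
    out
  }
  water <- pad(oil$water_conc)          # day x poly x layer
  frac <- pad(oil$oiled_cell_fraction)  # day x poly
  bottom <- pad(oil$bottom_conc)        # day x poly
  # mean concentration over the oiled cells only
  fr <- pmax(frac, 1e-12)
  unoiled <- array(as.vector(frac == 0), dim(water))
  conc_oiled <- water / as.vector(fr)   # recycles day x poly over layers
  conc_oiled[unoiled] <- 0
  bot_oiled <- bottom / fr
  bot_oiled[frac == 0] <- 0
  # body burdens
  phi_pel <- array(0, dim(water))
  for (l in seq_len(nl))
    phi_pel[, , l] <- body_burden_series(conc_oiled[, , l],
                                         params$mu_pelagic, params$rho)
  phi_ben <- body_burden_series(bot_oiled, params$mu_benthic, params$rho)
  K_pel <- if (params$K_applies_pelagic) params$K else 1
  # effects, down-weighted by oiled-cell fraction
  e_m_pel <- array(mortality_effect(phi_pel, params, K = K_pel),
                   dim(phi_pel)) * as.vector(frac)
  e_m_ben <- mortality_effect(phi_ben, params) * frac
  gp <- growth_effect(phi_pel, params, K = K_pel)
  gb <- growth_effect(phi_ben, params)
  e_g_pel <- array(gp$effect, dim(phi_pel)) * as.vector(frac)
  e_g_ben <- gb$effect * frac
  # per-group pelagic effect: weight layers by vertical distribution
  prof <- layer_profiles(web, geometry)  # group x poly x (nl water + sediment)
  m_oil <- array(0, c(n_days, np, ng), dimnames = list(NULL, NULL, web$groups$code))
  g_eff <- array(0, c(n_days, np, ng), dimnames = list(NULL, NULL, web$groups$code))
  m_pel_g <- array(0, c(n_days, np, ng))
  g_pel_g <- array(0, c(n_days, np, ng))
  for (g in which(web$groups$is_fish)) {
    wprof <- prof[g, , seq_len(nl), drop = FALSE][1, , ]  # poly x layer
    wprof <- wprof / pmax(rowSums(wprof), 1e-12)          # water-column share
    mp <- matrix(0, n_days, np)
    gpm <- matrix(0, n_days, np)
    for (l in seq_len(nl)) {
      mp <- mp + e_m_pel[, , l] * rep(wprof[, l], each = n_days)
      gpm <- gpm + e_g_pel[, , l] * rep(wprof[, l], each = n_days)
    }
    bf <- web$groups$benthic_frac[g]
    m_pel_g[, , g] <- mp
    g_pel_g[, , g] <- gpm
    m_oil[, , g] <- combine_modifiers(mp, e_m_ben, bf)
    g_eff[, , g] <- combine_modifiers(gpm, e_g_ben, bf)
  }
  g_mult <- 1 - g_eff
  g_mult[g_mult < 0] <- 0
  structure(list(m_oil = m_oil, g_mult = g_mult, g_eff = g_eff,
                 m_pelagic = m_pel_g, m_benthic = e_m_ben,
                 g_pelagic = g_pel_g, g_benthic = e_g_ben,
                 phi_pelagic = phi_pel, phi_benthic = phi_ben,
                 oiled_cell_fraction = frac,
                 benthic_frac = web$groups$benthic_frac,
                 n_days = n_days),
            class = "tox_forcing")
}
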