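#' Predation fluxes (Holling type II over the availability matrix)
#'
#' Per-layer, per-polygon multi-prey Holling type-II consumption: the
#' per-capita intake rate of a predator saturates at `1/handling`; prey are
#' taken in proportion to availability times local biomass density, with
#' gape limitation folded into the availability matrix and co-occurrence
#' enforced by the vertical profiles. Total loss of a prey cell is capped at
#' a fraction of its standing biomass per step; predator intake is reduced
#' consistently when the cap binds.
#'
#' @param state a `model_state`.
#' @param dt step length in days.
#' @return list with `prey_loss` (cell x polygon, mg N over the step),
#'   `intake_percap` (cell x polygon, mg N per individual over the step) and
#'   `consumption` (cell x cell, mg N, predator rows over prey columns,
#'   domain totals).
#' @export
predation_fluxes <- function(state, dt = 0.5) {
  cal <- state$calib
  nc <- cal$nc
  np <- state$n_polygons
  w <- state$sN + state$rN
  inv_area <- rep(1 / cal$area, each = nc)
  Bd <- state$N * w * inv_area
  # habitat refuge: the last few percent of initial local density is
  # inaccessible to predators, so depleted prey are not chased to extinction
  Bd <- pmax(Bd - cal$refuge_dens, 0)
  a <- cal$a_att
  h <- cal$h_hand
  L <- matrix(0, nc, np)
  Tsum <- matrix(0, nc, np)
  Tl <- vector("list", cal$nlz)
  ABl <- vector("list", cal$nlz)
  for (l in seq_len(cal$nlz)) {
    P <- cal$Pl[[l]]
    AB <- cal$A0 %*% (Bd * P)
    Irate <- a * AB / (1 + a * h * AB)
    Tloc <- state$N * P * Irate * dt
    ABl[[l]] <- AB
    Tl[[l]] <- Tloc
    Tsum <- Tsum + Tloc
    L <- L + (Bd * P) * crossprod(cal$A0, Tloc / pmax(AB, 1e-300))
  }
  B <- Bd * rep(cal$area, each = nc)   # accessible biomass
  cap <- cal$crop_cap * B
  scale <- ifelse(L > cap, cap / pmax(L, 1e-300), 1)
  consumption <- matrix(0, nc, nc)
  if (any(scale < 1)) {
    Tsum <- matrix(0, nc, np)
    for (l in seq_len(cal$nlz)) {
      P <- cal$Pl[[l]]
      Tsum <- Tsum + (Tl[[l]] / pmax(ABl[[l]], 1e-300)) *
        (cal$A0 %*% (Bd * P * scale))
    }
    L <- L * scale
  }
  # domain-total consumption matrix (predator x prey)
  for (l in seq_len(cal$nlz)) {
    P <- cal$Pl[[l]]
    W <- (Tl[[l]] / pmax(ABl[[l]], 1e-300))
    consumption <- consumption +
      (cal$A0 * ((W) %*% t(Bd * P * scale)))
  }
  list(prey_loss = L, intake_percap = Tsum / pmax(state$N, 1e-300) *
         (state$N > 0), consumption = consumption)
}

#' Growth update from assimilated intake
#'
#' Assimilated intake (scaled by the oil growth multiplier) net of
#' maintenance is allocated with priority to scheduled structural growth;
#' the reserve pool absorbs any surplus or deficit, and is floored at zero.
#' Structural weight never shrinks: under starvation the reserve declines
#' first, mirroring reabsorbable soft tissue.
#'
#' @param intake per-capita intake over the step (mg N per individual).
#' @param assimilation_efficiency fraction of intake assimilated.
#' @param g_mult oil growth multiplier in `[0, 1]`.
#' @param maintenance per-capita maintenance cost over the step (mg N).
#' @param ds_target scheduled structural growth over the step (mg N).
#' @param rN current reserve pool (mg N per individual).
#' @return list with `d_sN`, `d_rN` (applied changes) and `retained`
#'   (d_sN + d_rN, the net biomass change per individual).
#' @export
growth_update <- function(intake, assimilation_efficiency, g_mult,
                          maintenance = 0, ds_target = 0, rN = Inf) {
  net <- assimilation_efficiency * intake * g_mult - maintenance
  ds <- pmin(ds_target, pmax(net, 0))
  dr <- pmax(net - ds, -rN)
  if (!is.null(dim(net))) { dim(ds) <- dim(net); dim(dr) <- dim(net) }
  list(d_sN = ds, d_rN = dr, retained = ds + dr)
}

#' Non-predation mortality
#'
#' Applies survival `exp(-(m_l + m_q * B_local + m_oil + m_starv) * dt)` to
#' numbers. The quadratic term uses local group biomass density; starvation
#' mortality switches on when the reserve:structural ratio falls below the
#' condition floor. Only fish receive `m_oil`.
#'
#' @param state a `model_state`.
#' @param m_oil matrix polygon x group of per-day oil mortality (or `NULL`).
#' @param dt step length in days.
#' @return list with `survival` (cell x polygon) and `rate` (per day).
#' @export
natural_mortality <- function(state, m_oil = NULL, dt = 0.5) {
  cal <- state$calib
  nc <- cal$nc
  gi <- cal$cells$gi
  w <- state$sN + state$rN
  Bg <- rowsum(state$N * w, gi)                       # group x poly
  Bd_g <- Bg / rep(cal$area, each = nrow(Bg))
  rate <- cal$m_l + (cal$m_q_gp * Bd_g)[gi, , drop = FALSE]
  cond <- state$rN / pmax(state$sN, 1e-300)
  starv <- cal$starv_coef * (cal$cond_floor - cond) / cal$cond_floor
  starv[starv < 0] <- 0
  starv[!cal$is_fish_cell, ] <- 0
  rate <- rate + starv
  if (!is.null(m_oil)) {
    mo_cell <- t(m_oil)[gi, , drop = FALSE]           # cell x poly
    mo_cell[!cal$is_fish_cell, ] <- 0
    rate <- rate + mo_cell
  }
  list(survival = exp(-rate * dt), rate = rate)
}

#' Fishing fluxes under closures
#'
#' Local fishing mortality is the base rate scaled by `1 - closed_fraction`
#' for the cell's fleet in that polygon; effort is not reallocated, so F
#' elsewhere is unchanged when a polygon closes. Selectivity is knife-edge
#' at maturity (folded into the base rates).
#'
#' @param state a `model_state`.
#' @param closed matrix polygon x fleet of closed fractions (or `NULL`).
#' @param dt step length in days.
#' @return list with `frac` (cell x polygon fraction of numbers caught after
#'   natural mortality) and `F_eff` (per-day rates).
#' @export
fishing_fluxes <- function(state, closed = NULL, dt = 0.5) {
  cal <- state$calib
  np <- state$n_polygons
  Feff <- matrix(cal$F0_cell, cal$nc, np)
  if (!is.null(closed)) {
    open <- 1 - closed                                 # poly x fleet
    fl <- match(cal$fleet_of, colnames(closed))
    ok <- !is.na(fl)
    Feff[ok, ] <- Feff[ok, ] * t(open)[fl[ok], , drop = FALSE]
  }
  list(frac = 1 - exp(-Feff * dt), F_eff = Feff)
}

#' Seasonal migration and within-domain diffusion
#'
#' Density-dependent diffusion moves individuals toward under-occupied
#' adjacent polygons relative to the group's habitat preference (the
#' operator conserves numbers exactly). Scheduled groups emigrate a fraction
#' of numbers to an external pool over an autumn window and re-enter over a
#' spring window, with no mortality outside the domain.
#'
#' @param state a `model_state`.
#' @param doy day of the 365-day year.
#' @param dt step length in days.
#' @return updated state plus `imm`/`em` biomass fluxes (cell x polygon).
#' @export
migration_fluxes <- function(state, doy, dt = 0.5) {
  cal <- state$calib
  nc <- cal$nc
  np <- state$n_polygons
  imm <- em <- matrix(0, nc, np)
  w <- state$sN + state$rN
  g <- cal$cells$gi
  # preference-weighted diffusion: the same donor-valued operator moves
  # numbers and both nitrogen pools, so mass is conserved exactly
  for (gi in unique(g)) {
    M <- cal$Mdiff[[gi]]
    if (is.null(M)) next
    idx <- which(g == gi)
    d <- dt * cal$diffusion_rates[gi]
    invh <- rep(1 / pmax(cal$hab[gi, ], 1e-8), each = length(idx))
    N0 <- state$N[idx, , drop = FALSE]
    Ns <- N0 * state$sN[idx, , drop = FALSE]
    Nr <- N0 * state$rN[idx, , drop = FALSE]
    dN <- d * (N0 * invh) %*% M
    dNs <- d * (Ns * invh) %*% M
    dNr <- d * (Nr * invh) %*% M
    N1 <- N0 + dN
    state$N[idx, ] <- N1
    state$sN[idx, ] <- (Ns + dNs) / pmax(N1, 1e-300)
    state$rN[idx, ] <- (Nr + dNr) / pmax(N1, 1e-300)
    dB <- dNs + dNr
    imm[idx, ] <- imm[idx, ] + pmax(dB, 0)
    em[idx, ] <- em[idx, ] + pmax(-dB, 0)
  }
  # seasonal exchange with an external pool
  for (code in names(cal$seasonal)) {
    sch <- cal$seasonal[[code]]
    idx <- which(cal$cells$code == code)
    if (doy %in% sch$out_doy) {
      k <- 1 - (1 - sch$out_total)^(dt / length(sch$out_doy))
      moved <- state$N[idx, , drop = FALSE] * k
      mN <- rowSums(moved)
      tot <- state$ext_N[idx] + mN
      wm <- function(extv, cur) ifelse(tot > 0,
        (state$ext_N[idx] * extv + rowSums(moved * cur)) / pmax(tot, 1e-300),
        extv)
      state$ext_sN[idx] <- wm(state$ext_sN[idx], state$sN[idx, , drop = FALSE])
      state$ext_rN[idx] <- wm(state$ext_rN[idx], state$rN[idx, , drop = FALSE])
      state$ext_N[idx] <- tot
      state$N[idx, ] <- state$N[idx, ] - moved
      em[idx, ] <- em[idx, ] + moved * w[idx, , drop = FALSE]
    }
    if (doy %in% sch$in_doy && any(state$ext_N[idx] > 0)) {
      remaining <- max(sch$in_doy) - doy + 1
      back <- state$ext_N[idx] * min(dt / remaining, 1)
      share <- cal$hab[cal$cells$gi[idx][1], ]
      add <- outer(back, share)
      wext <- state$ext_sN[idx] + state$ext_rN[idx]
      # pool-average weights on re-entry
      tot <- state$N[idx, , drop = FALSE] + add
      mix <- function(cur, extv) (state$N[idx, , drop = FALSE] * cur +
                                    add * extv) / pmax(tot, 1e-300)
      state$sN[idx, ] <- mix(state$sN[idx, , drop = FALSE], state$ext_sN[idx])
      state$rN[idx, ] <- mix(state$rN[idx, , drop = FALSE], state$ext_rN[idx])
      state$N[idx, ] <- tot
      state$ext_N[idx] <- state$ext_N[idx] - back
      imm[idx, ] <- imm[idx, ] + add * wext
    }
  }
  list(state = state, imm = imm, em = em)
}

#' Annual recruitment and age-class promotion
#'
#' Beverton-Holt recruits from mature biomass enter the first age class at
#' the spawning event; their biomass is debited from the spawners' reserve
#' pools (gonad output), producing the seasonal saw-tooth in condition
#' factor. In the spill year recruits are scaled by `1 - loss_fraction`;
#' killed larvae are routed to detritus. Promotion moves a fixed fraction
#' `1/class_width` of each class up annually; the oldest class is a plus
#' group.
#'
#' @param state a `model_state`.
#' @param web the `food_web`.
#' @param larval_loss a `larval_loss_table` or `NULL`.
#' @param event `"recruit"` or `"promote"`.
#' @return updated state plus flux matrices `recruit_in`, `spawn_out`,
#'   `aging_net`, `det_in` (biomass, cell x polygon).
#' @export
recruitment_and_aging <- function(state, web, larval_loss = NULL,
                                  event = "recruit", frac = 1) {
  cal <- state$calib
  nc <- cal$nc
  np <- state$n_polygons
  recruit_in <- spawn_out <- aging_net <- det_in <- matrix(0, nc, np)
  g <- web$groups
  if (event == "recruit") {
    for (gi in which(g$is_fish)) {
      idx <- which(cal$cells$gi == gi)
      mt <- idx[cal$cells$age[idx] >= g$maturity_class[gi]]
      S <- sum(state$N[mt, , drop = FALSE] *
                 (state$sN[mt, , drop = FALSE] + state$rN[mt, , drop = FALSE]))
      rp <- cal$rec[gi, ]
      hst <- rp$steep
      R <- frac * (0.8 * rp$R0 * hst * S) /
        (0.2 * rp$S0 * (1 - hst) + (hst - 0.2) * S)
      loss <- 0
      if (!is.null(larval_loss)) {
        lf <- larval_loss$loss_fraction[match(g$code[gi], larval_loss$code)]
        if (is.finite(lf)) {
          if (lf < 0 || lf > 1) stop("larval loss fraction outside [0, 1]")
          loss <- lf
        }
      }
      w0 <- cal$w0_g[gi]
      sN0 <- w0 / (1 + cal$x_rs)
      rN0 <- w0 - sN0
      need <- R * w0
      avail <- sum(state$N[mt, , drop = FALSE] * state$rN[mt, , drop = FALSE])
      if (need > 0.8 * avail) R <- 0.8 * avail / w0
      need <- R * w0
      # debit gonad output proportionally from mature reserves
      if (need > 0 && avail > 0) {
        f <- need / avail
        spawn_out[mt, ] <- state$N[mt, , drop = FALSE] *
          state$rN[mt, , drop = FALSE] * f
        state$rN[mt, ] <- state$rN[mt, ] * (1 - f)
      }
      Rsurv <- R * (1 - loss)
      dead_mass <- R * loss * w0
      if (dead_mass > 0)
        det_in[cal$det_cell, ] <- det_in[cal$det_cell, ] +
          dead_mass * cal$hab[gi, ]
      # recruits enter class 1, mixing weights
      i1 <- idx[1]
      add <- Rsurv * cal$hab[gi, ]
      tot <- state$N[i1, ] + add
      state$sN[i1, ] <- (state$N[i1, ] * state$sN[i1, ] + add * sN0) /
        pmax(tot, 1e-300)
      state$rN[i1, ] <- (state$N[i1, ] * state$rN[i1, ] + add * rN0) /
        pmax(tot, 1e-300)
      state$N[i1, ] <- tot
      recruit_in[i1, ] <- add * w0
    }
    if (any(det_in > 0)) {
      state$N[cal$det_cell, ] <- state$N[cal$det_cell, ] + det_in[cal$det_cell, ]
    }
  } else {
    for (gi in which(g$is_fish)) {
      idx <- which(cal$cells$gi == gi)
      p <- 1 / g$age_years[gi]
      na <- length(idx)
      moved <- state$N[idx, , drop = FALSE] * p
      for (a in seq(na - 1, 1)) {
        src <- idx[a]; dst <- idx[a + 1]
        mN <- moved[a, ]
        tot <- state$N[dst, ] + mN
        state$sN[dst, ] <- (state$N[dst, ] * state$sN[dst, ] +
                              mN * state$sN[src, ]) / pmax(tot, 1e-300)
        state$rN[dst, ] <- (state$N[dst, ] * state$rN[dst, ] +
                              mN * state$rN[src, ]) / pmax(tot, 1e-300)
        wsrc <- state$sN[src, ] + state$rN[src, ]
        aging_net[dst, ] <- aging_net[dst, ] + mN * wsrc
        aging_net[src, ] <- aging_net[src, ] - mN * wsrc
        state$N[dst, ] <- tot
        state$N[src, ] <- state$N[src, ] - mN
      }
    }
  }
  list(state = state, recruit_in = recruit_in, spawn_out = spawn_out,
       aging_net = aging_net, det_in = det_in)
}

#' Advance the model by one step
#'
#' Applies, in order: predation, growth (with the oil growth multiplier),
#' natural + oil + starvation mortality, fishing under closures, migration,
#' and — on the scheduled days — annual promotion (day-of-year 1) and
#' recruitment (day-of-year 181, with larval losses in the spill year).
#' Unassimilated intake, maintenance excretion, dead bodies and killed
#' larvae are routed to the detritus pool; phytoplankton production draws on
#' detritus, closing the nitrogen loop. Non-fish groups never receive oil
#' modifiers. Returns the new state and a complete flux record whose signed
#' sum reproduces the biomass change exactly.
#'
#' @param state a `model_state`.
#' @param web the `food_web`.
#' @param m_oil matrix polygon x group per-day oil mortality, or `NULL`.
#' @param g_mult matrix polygon x group growth multiplier, or `NULL`.
#' @param closed matrix polygon x fleet closed fractions, or `NULL`.
#' @param larval_loss `larval_loss_table` applied at this year's recruitment
#'   event, or `NULL`.
#' @param dt step length in days (default 0.5).
#' @param events run the daily/annual events scheduled for this half step.
#' @return list with `state` and `fluxes` (biomass fluxes, cell x polygon:
#'   `pred_loss`, `growth`, `m1_loss`, `catch`, `imm`, `em`, `recruit_in`,
#'   `spawn_out`, `aging_net`, plus `consumption`, `catch_by_fleet`).
#' @export
step <- function(state, web, m_oil = NULL, g_mult = NULL, closed = NULL,
                 larval_loss = NULL, dt = 0.5, events = TRUE) {
  cal <- state$calib
  nc <- cal$nc
  np <- state$n_polygons
  if (any(!is.finite(state$N)) || any(state$N < -1e-9))
    stop("state blow-up: non-finite or negative numbers at day ", state$day)
  day <- state$day + dt
  today <- ceiling(day)
  doy <- (today - 1) %% 365 + 1

  fx <- list(pred_loss = matrix(0, nc, np), growth = matrix(0, nc, np),
             m1_loss = matrix(0, nc, np), catch = matrix(0, nc, np),
             imm = matrix(0, nc, np), em = matrix(0, nc, np),
             recruit_in = matrix(0, nc, np), spawn_out = matrix(0, nc, np),
             aging_net = matrix(0, nc, np),
             catch_by_fleet = stats::setNames(numeric(length(cal$fleets)),
                                              cal$fleets))
  B0 <- state$N * (state$sN + state$rN)

  # ---- annual events, once per scheduled day regardless of step size ----
  if (events && today > state$event_day) {
    state$event_day <- today
    if (doy == 1 && day > 1) {
      ra <- recruitment_and_aging(state, web, NULL, event = "promote")
      state <- ra$state
      fx$aging_net <- fx$aging_net + ra$aging_net
    }
    if (doy %in% cal$recruit_doys) {
      ra <- recruitment_and_aging(state, web, larval_loss, event = "recruit",
                                  frac = 1 / length(cal$recruit_doys))
      state <- ra$state
      fx$recruit_in <- fx$recruit_in + ra$recruit_in
      fx$spawn_out <- fx$spawn_out + ra$spawn_out
      fx$growth <- fx$growth + ra$det_in
    }
  }

  gi <- cal$cells$gi

  # ---- predation ----
  pf <- predation_fluxes(state, dt)
  w <- state$sN + state$rN
  dN_prey <- pf$prey_loss / pmax(w, 1e-300)
  state$N <- pmax(state$N - dN_prey, 0)
  fx$pred_loss <- pf$prey_loss
  fx$consumption <- pf$consumption

  # ---- growth ----
  gm_cell <- matrix(1, nc, np)
  if (!is.null(g_mult)) {
    gmc <- t(g_mult)[gi, , drop = FALSE]
    gmc[!cal$is_fish_cell, ] <- 1
    gm_cell <- gmc
  }
  intake <- pf$intake_percap
  fishc <- cal$is_fish_cell
  pid <- cal$pool_cell
  rfloor <- state$rN
  rfloor[pid, ] <- Inf   # pools shed biomass through numbers, not reserves
  gu <- growth_update(intake, cal$ae, gm_cell,
                      maintenance = cal$maint * w * dt,
                      ds_target = cal$ds_sched * dt, rN = rfloor)
  dsN <- gu$d_sN; drN <- gu$d_rN
  dsN[!fishc, ] <- 0
  drN[!fishc, ] <- 0
  # reserves saturate; surplus is excreted rather than hoarded
  drN <- pmin(drN, 1.3 * cal$x_rs * (state$sN + dsN) - state$rN)
  # pools grow/shrink in numbers (biomass with unit weight), not weight;
  # positive pool production tapers as local density exceeds its baseline;
  # the exponential map keeps the update exact for a constant rate
  poolgrow <- matrix(0, nc, np)
  pret <- pmax(gu$retained[pid, , drop = FALSE], -1)
  dens_fac <- 1.5 - 0.5 * (state$N[pid, , drop = FALSE] /
                             cal$pool_N0[pid, , drop = FALSE])
  dens_fac[dens_fac > 1.2] <- 1.2
  dens_fac[dens_fac < 0] <- 0
  pret <- ifelse(pret > 0, pret * dens_fac, pret)
  poolgrow[pid, ] <- state$N[pid, , drop = FALSE] * expm1(pret)
  growth_gain <- state$N * (dsN + drN) + poolgrow
  state$sN <- state$sN + dsN
  state$rN <- state$rN + drN
  state$N[pid, ] <- pmax(state$N[pid, , drop = FALSE] +
                           poolgrow[pid, , drop = FALSE], 0)
  fx$growth <- fx$growth + growth_gain
  # eaten mass not retained by any consumer settles to detritus
  det_gain_p <- colSums(pf$prey_loss) - colSums(growth_gain)
  # phytoplankton production draws on remineralised detritus; the carrying
  # capacity tracks the local detrital (nutrient) stock, so nitrogen parked
  # in detritus feeds back into production
  ph <- cal$phy_cell
  cap <- cal$phy_cap * pmax(state$N[cal$det_cell, ] / cal$det_N0, 0.05)
  # exact logistic step (Euler would over/undershoot at half-day steps)
  Pn <- state$N[ph, ]
  ert <- exp(cal$phy_r * dt)
  dphy <- cap * Pn * ert / pmax(cap + Pn * (ert - 1), 1e-300) - Pn
  dphy <- pmax(pmin(dphy, 0.9 * state$N[cal$det_cell, ]), 0)
  state$N[ph, ] <- state$N[ph, ] + dphy
  fx$growth[ph, ] <- fx$growth[ph, ] + dphy
  det_gain_p <- det_gain_p - dphy

  # ---- natural + oil + starvation mortality ----
  nm <- natural_mortality(state, m_oil, dt)
  w <- state$sN + state$rN
  dead <- state$N * (1 - nm$survival)
  state$N <- state$N * nm$survival
  fx$m1_loss <- dead * w
  det_gain_p <- det_gain_p + colSums(dead * w)
  state$N[cal$det_cell, ] <- state$N[cal$det_cell, ] + det_gain_p
  fx$growth[cal$det_cell, ] <- fx$growth[cal$det_cell, ] + det_gain_p

  # ---- fishing ----
  ff <- fishing_fluxes(state, closed, dt)
  caught <- state$N * ff$frac
  state$N <- state$N - caught
  fx$catch <- caught * w
  for (fl in cal$fleets) {
    sel <- cal$fleet_of == fl
    fx$catch_by_fleet[fl] <- sum(fx$catch[sel, , drop = FALSE])
  }

  # ---- migration (daily pieces applied each half step) ----
  mg <- migration_fluxes(state, doy, dt)
  state <- mg$state
  fx$imm <- mg$imm
  fx$em <- mg$em

  state$day <- day
  if (any(!is.finite(state$N)) || any(state$N < -1e-9))
    stop("state blow-up: non-finite or negative numbers at day ", day)
  list(state = state, fluxes = fx)
}
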