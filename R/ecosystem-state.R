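#' Initialise a calibrated model state
#'
#' Distributes each group's biomass over polygons via habitat/depth
#' preference maps, builds numbers-at-age from the target total mortality,
#' and balances the web so the initial state is near equilibrium:
#' predator rations are sized from scheduled growth, maintenance and
#' spawning output; diet availabilities are rebalanced so no prey is cropped
#' beyond a fraction of its production; residual (non-predation) linear and
#' quadratic mortality absorb the remainder of each group's target mortality;
#' Holling attack and handling constants are solved so realised per-capita
#' intake at the initial state equals the required ration; stock-recruit
#' parameters are anchored to the initial spawning biomass; and the
#' phytoplankton carrying capacity is set so production balances grazing.
#'
#' Vertical structure is separable: numbers are tracked per (group, age,
#' polygon) with a static per-group vertical profile over layers; use
#' [numbers_by_layer()] for the per-layer view.
#'
#' @param web a `food_web` from [gen_food_web()].
#' @param geometry a `spill_geometry`.
#' @param seed integer seed (habitat-map jitter only; dynamics are
#'   deterministic).
#' @param x_rs target reserve:structural nitrogen ratio (condition factor of
#'   a well-fed fish).
#' @param fleets fleet names.
#' @param crop_frac maximum fraction of a prey group's production that
#'   predation may claim at the initial state.
#' @param hab_jitter_sd lognormal sd of the habitat-map jitter (0 gives the
#'   deterministic template distribution).
#' @return A `model_state`.
#' @export
init_state <- function(web, geometry, seed = 1, x_rs = 2.3,
                       fleets = c("reef", "pelagic", "demersal"),
                       crop_frac = 0.6, hab_jitter_sd = 0.1) {
  g <- web$groups
  ng <- nrow(g)
  np <- geometry$n_polygons
  area <- geometry$polygons$area_km2
  tot_area <- sum(area)

  # ---- cells: one row per (group, age class) ----
  cells <- data.frame(
    gi = rep(seq_len(ng), g$n_age),
    age = unlist(lapply(g$n_age, seq_len))
  )
  cells$code <- g$code[cells$gi]
  nc <- nrow(cells)
  is_fish <- g$is_fish[cells$gi]

  # ---- weight-at-age (mg N per individual), vB cubed with a 0.5 y offset ----
  t0 <- 0.5
  w_start <- w_end <- w_mid <- numeric(nc)
  for (i in seq_len(nc)) {
    gi <- cells$gi[i]
    if (!g$is_fish[gi]) { w_start[i] <- w_end[i] <- w_mid[i] <- 1; next }
    ay <- g$age_years[gi]
    vb <- function(t) g$winf_mgN[gi] * (1 - exp(-g$k_vb[gi] * (t + t0)))^3
    a0 <- (cells$age[i] - 1) * ay
    w_start[i] <- vb(a0)
    w_end[i] <- vb(a0 + ay)
    w_mid[i] <- vb(a0 + ay / 2)
  }
  dw_sched <- ifelse(is_fish, (w_end - w_start) / (g$age_years[cells$gi] * 365), 0)

  # ---- habitat maps over polygons ----
  set.seed(seed)
  hab <- matrix(0, ng, np)
  bot <- geometry$polygons$bottom_depth
  for (gi in seq_len(ng)) {
    if (g$is_fish[gi]) {
      w <- exp(-(log(bot / g$pref_depth[gi]))^2 / (2 * 0.9^2)) * area
    } else {
      w <- area
    }
    w <- w * exp(stats::rnorm(np, 0, hab_jitter_sd))
    hab[gi, ] <- w / sum(w)
  }
  # forage pools concentrate where their consumers do (rich shelf benthos
  # under demersal fish, zooplankton under the planktivore field), so local
  # supply can sustain local demand
  demand_map <- function(prey_code) {
    d <- numeric(np)
    for (gi in seq_len(ng)) {
      av <- web$diet[g$code[gi], prey_code]
      if (av > 0) d <- d + av * g$B0[gi] * hab[gi, ]
    }
    if (sum(d) <= 0) rep(1 / np, np) else d / sum(d)
  }
  for (code in c("ZOO", "BEN")) {
    gi <- which(g$code == code)
    hab[gi, ] <- 0.6 * demand_map(code) + 0.4 * hab[gi, ]
  }
  det_gi <- which(g$code == "DET")
  hab[det_gi, ] <- 0.6 * hab[which(g$code == "BEN"), ] + 0.4 * hab[det_gi, ]

  # ---- numbers-at-age: stationary state of the annual event cycle ----
  # (decay to the spawning day, unit recruitment into class 1, decay to the
  # year boundary, promotion) so the day-1 snapshot carries no phase
  # transient; the recruitment scale that sustains it becomes R0
  Z0 <- g$Z0
  build_numbers <- function(Z0) {
    # joint stationary (numbers, weights) fixed point of the annual event
    # cycle the simulator implements: continuous mortality, scheduled weight
    # growth, recruitment into class 1 at day 181, fractional promotion with
    # weight mixing at the year boundary. Starting on this cycle leaves no
    # phase or biomass-production transient.
    N <- matrix(0, nc, np)
    R0_g <- numeric(ng)
    w_bar <- w_mid
    for (gi in seq_len(ng)) {
      idx <- which(cells$gi == gi)
      if (!g$is_fish[gi]) {
        N[idx, ] <- g$B0[gi] * hab[gi, ]  # pools: biomass with unit weight
        next
      }
      na <- g$n_age[gi]
      p1 <- 1 / g$age_years[gi]
      seg <- c(120, 30, 30, 185)   # day-1 -> pulses at 121/151/181 -> day-366
      dwy <- dw_sched[idx] * 365
      w0 <- w_start[idx[1]]
      n <- rep(1, na)
      wv <- w_mid[idx]
      for (it in 1:200) {
        for (k in 1:3) {
          n <- n * exp(-Z0[gi] * seg[k] / 365)
          wv <- wv + dwy * seg[k] / 365
          wv[1] <- (n[1] * wv[1] + (1 / 3) * w0) / (n[1] + 1 / 3)
          n[1] <- n[1] + 1 / 3
        }
        n <- n * exp(-Z0[gi] * seg[4] / 365)
        wv <- wv + dwy * seg[4] / 365
        moved <- n * p1
        stay <- n - moved
        wnew <- wv
        for (a in seq(na, 2)) {
          inn <- moved[a - 1]
          tot <- stay[a] + inn + if (a == na) moved[na] else 0
          wnew[a] <- (stay[a] * wv[a] + inn * wv[a - 1] +
                        (if (a == na) moved[na] * wv[na] else 0)) /
            max(tot, 1e-12)
        }
        n <- stay
        n[-1] <- n[-1] + moved[-na]
        n[na] <- n[na] + moved[na]
        wv <- wnew
      }
      scale <- g$B0[gi] / sum(n * wv)
      R0_g[gi] <- scale
      N[idx, ] <- outer(n * scale, hab[gi, ])
      w_bar[idx] <- wv
    }
    list(N = N, R0_g = R0_g, w_bar = w_bar)
  }
  bn <- build_numbers(Z0)
  N <- bn$N
  R0_g <- bn$R0_g
  w_mid <- bn$w_bar   # initial per-capita weights sit on the cycle

  # ---- layer profiles and per-layer cell matrices ----
  prof <- layer_profiles(web, geometry)        # group x poly x layer(+sed)
  nlz <- dim(prof)[3]
  Pl <- lapply(seq_len(nlz), function(l)
    matrix(prof[cells$gi, , l], nc, np))                       # nc x np each

  # ---- gape mask and availability over cells ----
  diet <- web$diet
  mask <- matrix(1, nc, nc)
  for (i in which(is_fish)) {
    ratio <- w_mid[i] / w_mid
    blocked <- is_fish & (ratio < g$gape_min[cells$gi[i]] |
                            ratio > g$gape_max[cells$gi[i]])
    mask[i, blocked] <- 0
  }

  fleet_of <- g$fleet[cells$gi]
  mature <- is_fish & cells$age >= g$maturity_class[cells$gi]
  F0_cell <- ifelse(mature, g$F0[cells$gi] / 365, 0)  # per day

  pool_ration <- c(ZOO = 0.12, BEN = 0.06)            # per day, per unit biomass
  pi_pool <- c(ZOO = 0.35 * pool_ration[["ZOO"]] - g$maint[g$code == "ZOO"],
               BEN = 0.25 * pool_ration[["BEN"]] - g$maint[g$code == "BEN"])
  phy_r <- 0.4                                        # phytoplankton growth, /day

  ration_pass <- function(Z0, N) {
    # per-capita required ration (mg N / ind / day) and recruitment anchors
    spawn_pc <- numeric(nc)
    R0 <- S0 <- numeric(ng)
    for (gi in which(g$is_fish)) {
      idx <- which(cells$gi == gi)
      R0[gi] <- R0_g[gi]
      mt <- idx[cells$age[idx] >= g$maturity_class[gi]]
      S0[gi] <- sum(N[mt, ] * w_mid[mt])
      spawn_pc[mt] <- R0[gi] * w_start[idx[1]] / max(sum(N[mt, ]), 1e-12) / 365
    }
    I_req <- numeric(nc)
    for (i in seq_len(nc)) {
      gi <- cells$gi[i]
      if (g$is_fish[gi]) {
        I_req[i] <- (dw_sched[i] + g$maint[gi] * w_mid[i] + spawn_pc[i]) /
          g$assim[gi]
      } else if (g$code[gi] %in% names(pool_ration)) {
        I_req[i] <- pool_ration[[g$code[gi]]]
      }
    }
    list(I_req = I_req, R0 = R0, S0 = S0)
  }

  dens0 <- g$B0 / tot_area

  build_A0 <- function(share) {
    A0 <- share[cells$gi, cells$gi] / rep(dens0[cells$gi], each = nc) * mask
    rs <- rowSums(A0)
    A0 <- A0 / pmax(rs, 1e-12)
    A0[rs <= 0, ] <- 0
    A0
  }
  solve_attack <- function(A0, I_req, h_hand, N) {
    Bd_cell <- 0.7 * N * w_mid / rep(area, each = nc)   # accessible (ex-refuge)
    ABl <- lapply(seq_len(nlz), function(l) A0 %*% (Bd_cell * Pl[[l]]))
    a_att <- numeric(nc)
    for (i in which(I_req > 0)) {
      wpoly <- N[i, ] / max(sum(N[i, ]), 1e-12)
      f <- function(a) {
        tot <- 0
        for (l in seq_len(nlz)) {
          ab <- ABl[[l]][i, ]
          tot <- tot + sum(wpoly * Pl[[l]][i, ] * a * ab /
                             (1 + a * h_hand[i] * ab))
        }
        tot - I_req[i]
      }
      a_att[i] <- if (f(1e8) < 0) 1e8 else
        stats::uniroot(f, c(1e-14, 1e8), tol = 1e-14)$root
    }
    a_att
  }
  forage_margin <- 1.08   # solve attack slightly above the bare ration so
                          # reserves can rebuild after lean spells

  # iterate diet shares against *realised* consumption at the initial state,
  # capping the crop on each prey at a fraction of its production
  calibrate <- function(Z0, N, share) {
    # production available to predation, per year
    pb <- ifelse(g$is_fish, Z0,
                 c(PHY = phy_r * 365 * 0.5,
                   ZOO = 365 * pi_pool[["ZOO"]],
                   BEN = 365 * pi_pool[["BEN"]], DET = 5)[g$code])
    rp <- ration_pass(Z0, N)
    h_hand <- ifelse(rp$I_req > 0, 1 / (3 * rp$I_req), 0)
    proto <- list(N = N, sN = matrix(w_mid / (1 + x_rs), nc, np),
                  rN = matrix(w_mid * x_rs / (1 + x_rs), nc, np),
                  n_polygons = np)
    proto$sN[!is_fish, ] <- 1
    proto$rN[!is_fish, ] <- 0
    M2cell <- NULL
    for (it in 1:8) {
      A0 <- build_A0(share)
      a_att <- solve_attack(A0, forage_margin * rp$I_req, h_hand, N)
      proto$calib <- list(nc = nc, area = area, a_att = a_att,
                          h_hand = h_hand, Pl = Pl, nlz = nlz, A0 = A0,
                          crop_cap = 0.9, cells = cells,
                          refuge_dens = 0.3 * N * w_mid / rep(area, each = nc))
      class(proto) <- "model_state"
      pf <- predation_fluxes(proto, dt = 1)
      Lg <- rowsum(rowSums(pf$prey_loss), cells$gi)[, 1] * 365
      M2 <- Lg / pmax(g$B0, 1e-12)
      sfac <- pmin(1, crop_frac * pb / pmax(M2, 1e-12))
      if (it < 8 && any(sfac < 0.98)) {
        share2 <- sweep(share, 2, sfac^0.8, "*")
        share <- share2 * rowSums(share) / pmax(rowSums(share2), 1e-12)
      } else {
        M2cell <- pf$prey_loss * 365 / pmax(N * w_mid, 1e-12)
        M2cell[N * w_mid <= 0] <- 0
        break
      }
    }
    list(share = share, A0 = build_A0(share), a_att = a_att, h_hand = h_hand,
         M2 = M2, M2cell = M2cell, I_req = rp$I_req, R0 = rp$R0, S0 = rp$S0)
  }

  cp <- calibrate(Z0, N, diet)
  Fg <- ifelse(g$is_fish, g$F0 * 0.6, 0)   # mature-only F diluted over ages
  Z0new <- ifelse(g$is_fish, pmax(Z0, cp$M2 + Fg + 0.1), Z0)
  if (any(Z0new > Z0 + 1e-9)) {
    Z0 <- Z0new
    bn <- build_numbers(Z0)
    N <- bn$N
    R0_g <- bn$R0_g
    w_mid <- bn$w_bar
    cp <- calibrate(Z0, N, cp$share)
  }
  A0 <- cp$A0
  a_att <- cp$a_att
  h_hand <- cp$h_hand

  # ---- residual mortality balances every (cell, polygon) at t = 0 ----
  Bg0 <- rowsum(N * w_mid, cells$gi)                 # group x polygon biomass
  Bd0loc <- Bg0 / rep(area, each = ng)               # local density
  Bd0 <- rowSums(Bg0) / tot_area
  # the density-dependent (quadratic) term takes a share of the *residual*
  # mortality left after realised predation and fishing, so every
  # (cell, polygon) is balanced at t = 0 and local density anchors the pull
  m_q_gp <- matrix(0, ng, np)   # local quadratic coefficient per density
  m_l_cell <- matrix(0, nc, np)
  for (gi in seq_len(ng)) {
    idx <- which(cells$gi == gi)
    dref <- pmax(Bd0loc[gi, ], 0.1 * Bd0[gi])
    if (g$is_fish[gi]) {
      resid <- pmax(Z0[gi] / 365 - cp$M2cell[idx, , drop = FALSE] / 365 -
                      F0_cell[idx], 0.05 / 365)
      wB <- N[idx, , drop = FALSE] * w_mid[idx]
      mq0 <- 0.5 * colSums(resid * wB) / pmax(colSums(wB), 1e-12)
      m_q_gp[gi, ] <- mq0 / dref
      m_l_cell[idx, ] <- pmax(resid - rep(mq0, each = length(idx)), 0.02 / 365)
    } else if (g$code[gi] %in% names(pi_pool)) {
      pp <- pi_pool[[g$code[gi]]]
      resid <- pmax(pp - cp$M2cell[idx, ] / 365, 1e-4)
      m_q_gp[gi, ] <- 0.6 * resid / dref
      m_l_cell[idx, ] <- 0.4 * resid
    }
  }
  # phytoplankton: local carrying capacity so production balances grazing
  phy_gi <- which(g$code == "PHY")
  phy_cell_i <- which(cells$gi == phy_gi)
  m_l_cell[phy_cell_i, ] <- 0.005
  graze_loc <- pmin(cp$M2cell[phy_cell_i, ] / 365 + 0.005, 0.8 * phy_r)
  phy_cap <- g$B0[phy_gi] * hab[phy_gi, ] / (1 - graze_loc / phy_r)

  # ---- stock-recruit ----
  rec <- data.frame(gi = seq_len(ng), R0 = cp$R0, S0 = cp$S0,
                    steep = g$steepness)
  # recruit entry weight = start-of-class-1 weight
  w0_g <- vapply(seq_len(ng), function(gi) {
    idx <- which(cells$gi == gi)
    w_start[idx[1]]
  }, 0)

  # ---- migration operators ----
  adj <- geometry$adjacency
  Mdiff <- vector("list", ng)
  for (gi in seq_len(ng)) {
    if (g$diffusion[gi] <= 0) next
    h <- pmax(hab[gi, ], 1e-8)
    M <- matrix(0, np, np)
    for (k in seq_len(nrow(adj))) {
      i <- adj[k, 1]; j <- adj[k, 2]
      m <- (h[i] + h[j]) / 2
      M[j, i] <- M[j, i] + m
      M[i, j] <- M[i, j] + m
      M[i, i] <- M[i, i] - m
      M[j, j] <- M[j, j] - m
    }
    Mdiff[[gi]] <- M
  }
  # cap diffusion so no polygon can shed more than half its numbers per day
  diffusion_rates <- g$diffusion
  for (gi in seq_len(ng)) {
    M <- Mdiff[[gi]]
    if (is.null(M)) next
    fmax <- diffusion_rates[gi] * max(-diag(M) / pmax(hab[gi, ], 1e-8))
    if (fmax > 0.5) diffusion_rates[gi] <- diffusion_rates[gi] * 0.5 / fmax
  }
  # seasonal schedule: large pelagics overwinter partly outside the domain
  seasonal <- list(LPF = list(out_doy = 335:355, out_total = 0.25,
                              in_doy = 60:80))

  calib <- list(
    cells = cells, nc = nc, is_fish_cell = is_fish, w_mid = w_mid,
    w_start = w_start, w_end = w_end, dw_sched = dw_sched,
    ds_sched = dw_sched / (1 + x_rs), x_rs = x_rs,
    A0 = A0, Pl = Pl, nlz = nlz, a_att = a_att, h_hand = h_hand,
    I_req = cp$I_req, ae = ifelse(is.na(g$assim[cells$gi]), 0,
                                  c(g$assim)[cells$gi]),
    maint = ifelse(is.na(g$maint[cells$gi]), 0, g$maint[cells$gi]),
    m_l = m_l_cell, m_q_gp = m_q_gp, F0_cell = F0_cell,
    fleet_of = fleet_of, fleets = fleets, mature = mature,
    rec = rec, w0_g = w0_g, phy_cap = phy_cap, phy_r = phy_r,
    phy_cell = which(cells$code == "PHY"),
    det_cell = which(cells$code == "DET"),
    zoo_cell = which(cells$code == "ZOO"),
    pool_cell = which(!is_fish &
                        !(cells$code %in% c("PHY", "DET"))),
    hab = hab, Mdiff = Mdiff, seasonal = seasonal,
    diffusion_rates = diffusion_rates,
    refuge_dens = 0.3 * N * w_mid / rep(area, each = nc),
    pool_N0 = pmax(N, 1e-12),
    det_N0 = pmax(N[which(cells$code == "DET"), ], 1e-12),
    cond_floor = 0.5 * x_rs, starv_coef = 0.01,
    recruit_doys = c(121, 151, 181),
    crop_cap = 0.9, Z0 = Z0, area = area, pi_pool = pi_pool,
    r0_per_ssb = ifelse(g$is_fish & cp$S0 > 0, R0_g / pmax(cp$S0, 1e-12), 0)
  )

  sN <- matrix(w_mid / (1 + x_rs), nc, np)
  rN <- matrix(w_mid * x_rs / (1 + x_rs), nc, np)
  sN[!is_fish, ] <- 1
  rN[!is_fish, ] <- 0

  structure(list(N = N, sN = sN, rN = rN,
                 ext_N = numeric(nc), ext_sN = w_mid / (1 + x_rs),
                 ext_rN = w_mid * x_rs / (1 + x_rs),
                 day = 0L, event_day = 0L, calib = calib, n_polygons = np,
                 geometry_seed = geometry$seed, seed = seed),
            class = "model_state")
}

#' Biomass per group and polygon
#'
#' @param state a `model_state`.
#' @return matrix group x polygon of biomass (mg N).
#' @export
state_biomass <- function(state) {
  cal <- state$calib
  B <- state$N * (state$sN + state$rN)
  rowsum(B, cal$cells$gi)
}

#' Numbers by layer
#'
#' Expands the separable state onto the (group, age, polygon, layer) index
#' using the static vertical profiles: pelagic-flagged groups have zero
#' numbers in the sediment layer, benthic groups live only there.
#'
#' @param state a `model_state`.
#' @param web,geometry the objects the state was built from.
#' @return array cell x polygon x layer of numbers.
#' @export
numbers_by_layer <- function(state, web, geometry) {
  cal <- state$calib
  out <- array(0, c(cal$nc, state$n_polygons, cal$nlz))
  for (l in seq_len(cal$nlz)) out[, , l] <- state$N * cal$Pl[[l]]
  out
}

#' Re-balance a state in place
#'
#' Re-anchors the calibration at the current state: attack rates are
#' re-solved so realised per-capita intake meets the required ration at
#' today's prey field; residual linear and quadratic mortality absorb the
#' difference between target mortality and today's realised predation;
#' stock-recruit parameters, prey refuges, pool baselines and the
#' phytoplankton carrying capacity are re-anchored. Used together with a
#' burn-in run to produce a demo ecosystem that sits on its own attractor.
#'
#' @param state a `model_state` (typically after a burn-in run).
#' @param web the `food_web`.
#' @return the re-balanced `model_state`.
#' @export
rebalance_state <- function(state, web) {
  cal <- state$calib
  g <- web$groups
  ng <- nrow(g)
  nc <- cal$nc
  np <- state$n_polygons
  cells <- cal$cells
  N <- state$N
  w <- state$sN + state$rN
  area <- cal$area

  # recruitment anchors and required rations at the current state
  spawn_pc <- numeric(nc)
  R0 <- S0 <- numeric(ng)
  for (gi in which(g$is_fish)) {
    idx <- which(cells$gi == gi)
    mt <- idx[cells$age[idx] >= g$maturity_class[gi]]
    R0[gi] <- cal$r0_per_ssb[gi] *
      sum(N[mt, , drop = FALSE] * w[mt, , drop = FALSE])
    S0[gi] <- sum(N[mt, , drop = FALSE] * w[mt, , drop = FALSE])
    spawn_pc[mt] <- R0[gi] * cal$w_start[idx[1]] /
      max(sum(N[mt, , drop = FALSE]), 1e-12) / 365
  }
  I_req <- numeric(nc)
  for (i in seq_len(nc)) {
    gi <- cells$gi[i]
    if (g$is_fish[gi]) {
      I_req[i] <- (cal$dw_sched[i] + g$maint[gi] * cal$w_mid[i] +
                     spawn_pc[i]) / g$assim[gi]
    } else if (!is.null(cal$pi_pool) && cells$code[i] %in% c("ZOO", "BEN")) {
      I_req[i] <- cal$I_req[i]   # pool rations are per unit biomass, fixed
    }
  }
  h_hand <- ifelse(I_req > 0, 1 / (3 * I_req), 0)

  # refuges and accessible prey at today's densities
  refuge <- 0.3 * N * w / rep(area, each = nc)
  Bd_acc <- 0.7 * N * w / rep(area, each = nc)
  ABl <- lapply(seq_len(cal$nlz), function(l) cal$A0 %*% (Bd_acc * cal$Pl[[l]]))
  a_att <- numeric(nc)
  for (i in which(I_req > 0)) {
    wpoly <- N[i, ] / max(sum(N[i, ]), 1e-12)
    f <- function(a) {
      tot <- 0
      for (l in seq_len(cal$nlz)) {
        ab <- ABl[[l]][i, ]
        tot <- tot + sum(wpoly * cal$Pl[[l]][i, ] * a * ab /
                           (1 + a * h_hand[i] * ab))
      }
      tot - 1.08 * I_req[i]
    }
    a_att[i] <- if (f(1e8) < 0) 1e8 else
      stats::uniroot(f, c(1e-14, 1e8), tol = 1e-14)$root
  }
  state$calib$a_att <- a_att
  state$calib$h_hand <- h_hand
  state$calib$I_req <- I_req
  state$calib$refuge_dens <- refuge
  state$calib$rec <- data.frame(gi = seq_len(ng), R0 = R0, S0 = S0,
                                steep = g$steepness)

  # realised predation at the re-anchored state
  pf <- predation_fluxes(state, dt = 1)
  M2cell <- pf$prey_loss * 365 / pmax(N * w, 1e-12)
  M2cell[N * w <= 0] <- 0
  Bg0 <- rowsum(N * w, cells$gi)
  Bd0loc <- Bg0 / rep(area, each = ng)
  Bd0 <- rowSums(Bg0) / sum(area)
  m_q_gp <- matrix(0, ng, np)
  m_l_cell <- matrix(0, nc, np)
  for (gi in seq_len(ng)) {
    idx <- which(cells$gi == gi)
    dref <- pmax(Bd0loc[gi, ], 0.1 * Bd0[gi])
    if (g$is_fish[gi]) {
      # residual mortality balances measured biomass production (individual
      # growth plus recruitment) against realised predation and fishing,
      # polygon by polygon
      wB <- N[idx, , drop = FALSE] * w[idx, , drop = FALSE]
      prod_p <- colSums(N[idx, , drop = FALSE] * cal$dw_sched[idx]) +
        R0[gi] * cal$w0_g[gi] * cal$hab[gi, ] / 365
      cons_p <- colSums(wB * (M2cell[idx, , drop = FALSE] / 365 +
                                cal$F0_cell[idx]))
      Bp <- pmax(colSums(wB), 1e-12)
      r_res <- pmax(prod_p - cons_p, 0.02 / 365 * Bp) / Bp
      m_q_gp[gi, ] <- 0.5 * r_res / dref
      m_l_cell[idx, ] <- rep(0.5 * r_res, each = length(idx))
    } else if (cells$code[idx[1]] %in% c("ZOO", "BEN")) {
      pp <- cal$pi_pool[[cells$code[idx[1]]]]
      resid <- pmax(pp - M2cell[idx, ] / 365, 1e-4)
      m_q_gp[gi, ] <- 0.6 * resid / dref
      m_l_cell[idx, ] <- 0.4 * resid
    }
  }
  phy_gi <- which(g$code == "PHY")
  phy_cell_i <- which(cells$gi == phy_gi)
  m_l_cell[phy_cell_i, ] <- 0.005
  graze_loc <- pmin(M2cell[phy_cell_i, ] / 365 + 0.005, 0.8 * cal$phy_r)
  state$calib$phy_cap <- N[phy_cell_i, ] / (1 - graze_loc / cal$phy_r)
  state$calib$m_l <- m_l_cell
  state$calib$m_q_gp <- m_q_gp
  state$calib$pool_N0 <- pmax(N, 1e-12)
  state$calib$det_N0 <- pmax(N[which(cells$code == "DET"), ], 1e-12)
  # recruitment re-anchored to numbers stationarity of class 1 under the
  # realised mortality just set, honouring the three spawning pulses
  for (gi in which(g$is_fish)) {
    idx <- which(cells$gi == gi)
    i1 <- idx[1]
    p1 <- 1 / g$age_years[gi]
    wB <- N[i1, ] * w[i1, ]
    z1 <- 365 * sum((M2cell[i1, ] / 365 + cal$F0_cell[i1] + m_l_cell[i1, ] +
                       m_q_gp[gi, ] * Bd0loc[gi, ]) * wB) / max(sum(wB), 1e-12)
    sfun <- function(d) exp(-z1 * d / 365)
    N1 <- sum(N[i1, ])
    # pre-promotion stationarity: carry-over plus the three decayed pulses
    R0n <- N1 * (1 - (1 - p1) * sfun(365)) /
      ((sfun(245) + sfun(215) + sfun(185)) / 3)
    state$calib$rec$R0[gi] <- R0n
  }
  # repair body condition: the packaged state starts well-fed
  fish <- cal$is_fish_cell
  state$rN[fish, ] <- pmax(state$rN[fish, ], 0.9 * cal$x_rs *
                             state$sN[fish, ])
  state
}

#' Run a state forward without forcings
#'
#' @param state a `model_state`; @param web the `food_web`.
#' @param days number of days to integrate (two half-day steps per day).
#' @return the advanced `model_state`.
#' @export
run_unforced <- function(state, web, days) {
  for (k in seq_len(2 * days)) state <- step(state, web, dt = 0.5)$state
  state
}
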