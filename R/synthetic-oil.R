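#' Generate a synthetic gridded PAH concentration field
#'
#' Kernel-advection surrogate for a point-source oil release: each release
#' day injects a Gaussian blob of PAH mass into a surface layer and a deep
#' layer at the release site; blobs then drift, spread diffusively
#' (`sigma^2` grows linearly in time) and decay at a first-order rate.
#' Daily snapshots are produced on the geometry's grid for `track_days`
#' days; injection stops after `release_days`. The deep plume and the
#' surface slick drift independently. A per-day mass budget
#' (injected, decayed, advected out of the domain) is returned and closes
#' exactly against the field's total mass.
#'
#' @param geometry a `spill_geometry`.
#' @param release_site `c(lon, lat)` of the source.
#' @param release_depth depth (m) of the subsurface release, placing the
#'   deep plume in the corresponding water layer.
#' @param release_days number of days with new injection (default 87).
#' @param track_days number of days tracked (default 167; `>= release_days`).
#' @param surface_deep_fractions mass split `c(surface, deep)`, summing to 1.
#' @param amount daily injected PAH mass, in ppb * km^2 per layer-metre
#'   equivalents (sets the concentration scale).
#' @param decay_rate first-order loss rate (per day, >= 0).
#' @param drift_surface,drift_deep advection velocity `c(dlon, dlat)` in
#'   degrees per day for the two blobs.
#' @param sigma0 initial blob standard deviation (degrees).
#' @param diffusivity horizontal diffusivity (degrees^2 per day).
#' @param seed integer seed (small jitter on daily drift).
#' @return An `oil_field`: concentration array `conc` (day x layer x cell,
#'   ppb), the mass budget table, and grid/release descriptors.
#' @export
gen_oil_field <- function(geometry, release_site = NULL, release_depth = 1100,
                          release_days = 87, track_days = 167,
                          surface_deep_fractions = c(0.45, 0.55),
                          amount = 40000, decay_rate = 0.01,
                          drift_surface = c(0.008, 0.03),
                          drift_deep = c(-0.012, 0.006),
                          sigma0 = 0.2, diffusivity = 0.004, seed = 1) {
  if (!inherits(geometry, "spill_geometry")) stop("geometry must be a spill_geometry")
  if (track_days < release_days) stop("track_days must be >= release_days")
  if (decay_rate < 0) stop("decay_rate must be non-negative")
  if (any(surface_deep_fractions < 0) ||
      abs(sum(surface_deep_fractions) - 1) > 1e-9)
    stop("surface_deep_fractions must be non-negative and sum to 1")
  set.seed(seed)
  if (is.null(release_site))
    release_site <- c(mean(geometry$lon_range), mean(geometry$lat_range) - 0.4)
  nl <- geometry$n_layers
  deep_layer <- min(layer_at_depth(geometry, release_depth), nl)
  ncell <- geometry$nx * geometry$ny
  conc <- array(0, c(track_days, nl, ncell))
  clon <- geometry$cells$lon
  clat <- geometry$cells$lat
  ca <- geometry$cell_area_km2
  # per-day jittered drift paths (cumulative displacement), shared by blobs
  jit <- cbind(stats::rnorm(track_days, 0, 0.004), stats::rnorm(track_days, 0, 0.004))
  disp_s <- apply(rbind(0, matrix(drift_surface, track_days - 1, 2, byrow = TRUE) +
                          jit[-1, ]), 2, cumsum)
  disp_d <- apply(rbind(0, matrix(drift_deep, track_days - 1, 2, byrow = TRUE) +
                          jit[-1, ] * 0.5), 2, cumsum)
  masses <- amount * surface_deep_fractions
  layers <- c(1L, deep_layer)
  disp <- list(disp_s, disp_d)
  budget <- data.frame(day = seq_len(track_days), injected = 0,
                       decayed = 0, advected_out = 0, residual = 0)
  # in-domain fraction bookkeeping per blob: q[release r, day d]
  for (b in 1:2) {
    if (masses[b] <= 0) next
    l <- layers[b]
    qprev <- numeric(release_days)
    for (d in seq_len(track_days)) {
      rs <- seq_len(min(d, release_days))
      f_now <- masses[b] * exp(-decay_rate * (d - rs))
      f_prev <- masses[b] * exp(-decay_rate * (d - 1 - rs))
      for (r in rs) {
        age <- d - r
        ctr <- release_site + disp[[b]][d, ] - disp[[b]][r, ]
        s2 <- sigma0^2 + 2 * diffusivity * age
        w <- exp(-((clon - ctr[1])^2 + (clat - ctr[2])^2) / (2 * s2))
        w <- w * geometry$grid_resolution^2 / (2 * pi * s2)  # continuous kernel
        q <- sum(w)                      # in-domain fraction of the blob
        conc[d, l, ] <- conc[d, l, ] + f_now[r] * w / ca
        if (age == 0) {
          budget$injected[d] <- budget$injected[d] + f_now[r] * q
        } else {
          budget$decayed[d] <- budget$decayed[d] +
            (f_prev[r] - f_now[r]) * qprev[r]
          budget$advected_out[d] <- budget$advected_out[d] +
            f_now[r] * (qprev[r] - q)
        }
        qprev[r] <- q
      }
    }
  }
  total <- apply(conc, 1, sum) * ca
  budget$residual <- total
  structure(list(conc = conc, release_site = release_site,
                 release_depth = release_depth, deep_layer = deep_layer,
                 release_days = release_days, track_days = track_days,
                 n_layers = nl, nx = geometry$nx, ny = geometry$ny,
                 cell_area_km2 = ca, decay_rate = decay_rate,
                 budget = budget, seed = seed),
            class = "oil_field")
}

#' Total in-domain PAH mass of an oil field, per day
#'
#' @param field an `oil_field`.
#' @return numeric vector over days (ppb * km^2 units).
#' @export
oil_total_mass <- function(field) {
  apply(field$conc, 1, sum) * field$cell_area_km2
}
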