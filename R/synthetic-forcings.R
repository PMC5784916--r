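#' Generate an emergency fishery closure schedule
#'
#' Emulates the spatiotemporal shape of the emergency closures: a closed
#' footprint centred on the polygon containing the release site that grows
#' during the first phase of the window, holds, then shrinks to nothing by
#' the end. Per-day closed fractions per polygon and fleet lie in `[0, 1]`;
#' the schedule is zero outside the window. During the growth phase the
#' closed area is non-decreasing day over day.
#'
#' @param geometry a `spill_geometry`.
#' @param release_site `c(lon, lat)`; defaults to the domain centre used by
#'   [gen_oil_field()].
#' @param start_day first simulation day of the window.
#' @param duration_days window length (default 365, the emergency-closure
#'   duration).
#' @param peak_fraction maximum closed fraction at the footprint centre,
#'   in `[0, 1]`.
#' @param fleets fleet names the schedule applies to.
#' @param seed integer seed (unused randomness reserved; kept for a uniform
#'   generator interface).
#' @return A `closure_schedule`: array `closed` (day-in-window x polygon x
#'   fleet) plus `start_day` and `duration_days`.
#' @export
gen_closures <- function(geometry, release_site = NULL, start_day = 110,
                         duration_days = 365, peak_fraction = 0.8,
                         fleets = c("reef", "pelagic", "demersal"), seed = 1) {
  if (duration_days < 1) stop("duration_days must be >= 1")
  if (peak_fraction < 0 || peak_fraction > 1)
    stop("peak_fraction must lie in [0, 1]")
  set.seed(seed)
  if (is.null(release_site))
    release_site <- c(mean(geometry$lon_range), mean(geometry$lat_range) - 0.4)
  np <- geometry$n_polygons
  cen <- cbind(tapply(geometry$cells$lon, geometry$cells$polygon, mean),
               tapply(geometry$cells$lat, geometry$cells$polygon, mean))
  dist <- sqrt((cen[, 1] - release_site[1])^2 + (cen[, 2] - release_site[2])^2)
  grow <- ceiling(duration_days / 3)
  rmax <- max(dist) * 0.8
  closed <- array(0, c(duration_days, np, length(fleets)),
                  dimnames = list(NULL, NULL, fleets))
  for (d in seq_len(duration_days)) {
    r <- if (d <= grow) rmax * d / grow
         else rmax * (duration_days - d) / (duration_days - grow)
    f <- peak_fraction * pmax(0, 1 - dist / max(r, 1e-9))
    closed[d, , ] <- f
  }
  structure(list(closed = closed, start_day = start_day,
                 duration_days = duration_days, fleets = fleets,
                 peak_fraction = peak_fraction),
            class = "closure_schedule")
}

#' Closed fraction per polygon and fleet on a simulation day
#'
#' @param schedule a `closure_schedule` (or `NULL` for no closures).
#' @param day simulation day.
#' @param n_polygons,fleets dimensions of the returned matrix.
#' @return matrix polygon x fleet of closed fractions (zero outside the
#'   window).
#' @export
closed_fraction <- function(schedule, day, n_polygons,
                            fleets = c("reef", "pelagic", "demersal")) {
  out <- matrix(0, n_polygons, length(fleets), dimnames = list(NULL, fleets))
  if (is.null(schedule)) return(out)
  k <- day - schedule$start_day + 1
  if (k >= 1 && k <= schedule$duration_days) {
    sub <- schedule$closed[k, , , drop = FALSE]
    for (f in schedule$fleets) if (f %in% fleets) out[, f] <- sub[1, , f]
  }
  out
}

#' Generate per-group larval loss fractions
#'
#' Draws one loss fraction per fish group from a normal distribution
#' truncated to `[0, 1]` whose *post-truncation* moments match the supplied
#' mean and sd (parent parameters are solved numerically), emulating the
#' reported spill-year larval exposure of 5.8% (sigma = 4.5%) under the
#' bounding assumption that every exposed larva is killed. Non-fish groups
#' get zero. `sd = 0` gives every group exactly `mean`.
#'
#' @param web a `food_web` (or a data.frame of groups with `is_fish`).
#' @param mean,sd target moments of the loss distribution, both >= 0.
#' @param seed integer seed.
#' @return A `larval_loss_table`: data.frame with `code` and `loss_fraction`
#'   in `[0, 1]`.
#' @export
gen_larval_loss <- function(web, mean = 0.058, sd = 0.045, seed = 1) {
  if (mean < 0 || sd < 0) stop("mean and sd must be non-negative")
  groups <- if (inherits(web, "food_web")) web$groups else web
  set.seed(seed)
  n <- nrow(groups)
  loss <- numeric(n)
  fish <- groups$is_fish
  if (sd == 0) {
    loss[fish] <- min(max(mean, 0), 1)
  } else {
    par <- truncnorm_match(mean, sd)
    loss[fish] <- rtrunc01(sum(fish), par[1], par[2])
  }
  structure(data.frame(code = groups$code, loss_fraction = loss,
                       stringsAsFactors = FALSE),
            class = c("larval_loss_table", "data.frame"))
}

# Moments of N(m, s^2) truncated to [0, 1].
truncnorm_moments <- function(m, s) {
  a <- (0 - m) / s
  b <- (1 - m) / s
  Z <- stats::pnorm(b) - stats::pnorm(a)
  d <- (stats::dnorm(a) - stats::dnorm(b)) / Z
  mu <- m + s * d
  v <- s^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / Z - d^2)
  c(mu, sqrt(max(v, 0)))
}

# Solve parent (m, s) so the [0,1]-truncated normal has the target moments.
truncnorm_match <- function(mean, sd) {
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]))
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  c(fit$par[1], exp(fit$par[2]))
}

# Rejection sampler for N(m, s^2) truncated to [0, 1].
rtrunc01 <- function(n, m, s) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, m, s)
    out <- c(out, x[x >= 0 & x <= 1])
  }
  out[seq_len(n)]
}
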