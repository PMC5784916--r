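#' Relative biomass series per guild
#'
#' Guild-summed biomass of the impacted run divided by the baseline, over a
#' polygon subset. The subset defaults to the heavily impacted polygons: the
#' top fraction of polygons ranked by greatest proportional fish-biomass
#' change (minimum over months of impacted/baseline), mirroring how spill
#' assessments focus on the most affected areas; pass `polygon_subset`
#' explicitly to override.
#'
#' @param impacted,baseline paired `run_output`s on the same calendar and
#'   geometry.
#' @param polygon_subset integer polygon ids, or `NULL` to apply the
#'   greatest-change rule.
#' @param top_frac fraction of polygons kept by the greatest-change rule.
#' @param guilds aggregate by guild (default) or by functional group.
#' @return list with `ratio` (month x guild matrix), `months`, `subset`.
#' @export
relative_biomass <- function(impacted, baseline, polygon_subset = NULL,
                             top_frac = 0.25, guilds = TRUE) {
  check_paired(impacted, baseline)
  if (is.null(polygon_subset))
    polygon_subset <- impacted_polygons(impacted, baseline, top_frac)
  keep <- if (guilds) impacted$groups$is_fish else rep(TRUE, nrow(impacted$groups))
  glab <- if (guilds) impacted$groups$guild[keep] else impacted$groups$code[keep]
  agg <- function(run) {
    sub <- run$biomass[, keep, polygon_subset, drop = FALSE]
    tot <- apply(sub, c(1, 2), sum)           # month x group
    t(rowsum(t(tot), glab))                   # month x guild
  }
  bi <- agg(impacted)
  bb <- agg(baseline)
  ratio <- bi / pmax(bb, 1e-300)
  list(ratio = ratio, months = impacted$months, subset = polygon_subset,
       impacted_label = impacted$label)
}

# Heavily impacted polygons: greatest proportional fish-biomass change.
impacted_polygons <- function(impacted, baseline, top_frac = 0.25) {
  fish <- which(impacted$groups$is_fish)
  bi <- apply(impacted$biomass[, fish, , drop = FALSE], c(1, 3), sum)
  bb <- apply(baseline$biomass[, fish, , drop = FALSE], c(1, 3), sum)
  worst <- apply(bi / pmax(bb, 1e-300), 2, min)
  k <- max(1, round(top_frac * length(worst)))
  order(worst)[seq_len(k)]
}

check_paired <- function(a, b) {
  if (!inherits(a, "run_output") || !inherits(b, "run_output"))
    stop("inputs must be run_output objects")
  if (length(a$months) != length(b$months) ||
      !identical(dim(a$biomass), dim(b$biomass)))
    stop("runs do not share calendar and geometry")
}

#' Biomass minimum and its timing
#'
#' Global minimum of each relative-biomass series and the month in which it
#' occurs, counted from the spill date. Ties take the earliest month; a
#' series that never drops below 1 reports its minimum with month `NA`.
#'
#' @param comparison from [relative_biomass()].
#' @param spill_day simulation day of the spill (to convert months).
#' @return data.frame with `guild`, `min_ratio`, `month_of_min` (months
#'   after the spill).
#' @export
biomass_minimum <- function(comparison, spill_day = 110) {
  r <- comparison$ratio
  spill_month <- spill_day / (365 / 12)
  out <- data.frame(guild = colnames(r), min_ratio = NA_real_,
                    month_of_min = NA_real_)
  for (j in seq_len(ncol(r))) {
    out$min_ratio[j] <- min(r[, j])
    if (out$min_ratio[j] < 1) {
      m <- which.min(r[, j])                      # earliest on ties
      out$month_of_min[j] <- m - spill_month
    }
  }
  out
}

#' Recovery time relative to baseline
#'
#' First time after the biomass minimum at which the relative series reaches
#' the recovery threshold and stays at or above it for 12 consecutive
#' months. A series that never drops below the threshold has recovery time
#' 0; a series that never sustains the threshold within the horizon is `DNR`
#' (did not recover), returned as `NA` with `dnr = TRUE`.
#'
#' @param comparison from [relative_biomass()].
#' @param threshold recovery criterion (default 0.99, i.e. 99% of the
#'   no-oil biomass).
#' @param sustain_months months the threshold must be held (default 12).
#' @param spill_day simulation day of the spill.
#' @return data.frame with `guild`, `recovery_years`, `dnr`.
#' @export
recovery_time <- function(comparison, threshold = 0.99, sustain_months = 12,
                          spill_day = 110) {
  r <- comparison$ratio
  spill_month <- spill_day / (365 / 12)
  out <- data.frame(guild = colnames(r), recovery_years = NA_real_,
                    dnr = FALSE)
  for (j in seq_len(ncol(r))) {
    x <- r[, j]
    if (min(x) >= threshold) { out$recovery_years[j] <- 0; next }
    m0 <- which.min(x)
    ok <- x >= threshold
    rec <- NA_real_
    for (m in seq(m0, length(x))) {
      if (ok[m] && (m + sustain_months - 1) <= length(x) &&
          all(ok[m:(m + sustain_months - 1)])) {
        rec <- (m - 1 - spill_month) / 12
        break
      }
    }
    if (is.na(rec)) out$dnr[j] <- TRUE else out$recovery_years[j] <- max(rec, 0)
  }
  out
}

#' Age structure metrics
#'
#' Relative age composition per fish group and the mature-to-immature
#' numbers ratio over time, using each group's maturity age, aggregated
#' over a polygon subset.
#'
#' @param run a `run_output`.
#' @param polygon_subset polygons to include (default all).
#' @return list with `age_proportions` (month x cell data of per-age shares
#'   within group) and `mature_ratio` (month x group).
#' @export
age_structure_metrics <- function(run, polygon_subset = NULL) {
  cells <- run$cells
  if (is.null(polygon_subset)) polygon_subset <- seq_len(dim(run$numbers)[3])
  N <- apply(run$numbers[, , polygon_subset, drop = FALSE], c(1, 2), sum)
  g <- run$groups
  fishg <- which(g$is_fish)
  prop <- N
  ratio <- matrix(NA_real_, nrow(N), nrow(g),
                  dimnames = list(NULL, g$code))
  for (gi in fishg) {
    idx <- which(cells$gi == gi)
    tot <- rowSums(N[, idx, drop = FALSE])
    prop[, idx] <- N[, idx, drop = FALSE] / pmax(tot, 1e-300)
    mt <- idx[cells$age[idx] >= g$maturity_class[gi]]
    im <- setdiff(idx, mt)
    ratio[, gi] <- rowSums(N[, mt, drop = FALSE]) /
      pmax(rowSums(N[, im, drop = FALSE]), 1e-300)
  }
  list(age_proportions = prop, mature_ratio = ratio, cells = cells)
}

#' Condition factor series
#'
#' Biomass-weighted mean reserve:structural nitrogen ratio per guild. High
#' values indicate good body condition; spawning produces a seasonal
#' saw-tooth.
#'
#' @param run a `run_output`.
#' @return matrix month x guild.
#' @export
condition_factor <- function(run) {
  cells <- run$cells
  g <- run$groups
  fish <- g$is_fish[cells$gi]
  Bw <- run$sN + run$rN                  # per-capita weight proxy per cell
  glab <- g$guild[cells$gi]
  nm <- sort(unique(glab[fish]))
  out <- matrix(NA_real_, nrow(run$rN), length(nm),
                dimnames = list(NULL, nm))
  Ntot <- apply(run$numbers, c(1, 2), sum)
  for (k in seq_along(nm)) {
    idx <- which(glab == nm[k] & fish)
    wgt <- Ntot[, idx, drop = FALSE] * run$sN[, idx, drop = FALSE]
    out[, k] <- rowSums(run$rN[, idx, drop = FALSE] *
                          Ntot[, idx, drop = FALSE]) /
      pmax(rowSums(wgt), 1e-300)
  }
  out
}

#' Percentile of a value within pre-spill condition factors
#'
#' Locates a condition-factor value within the distribution of all guilds'
#' pre-spill monthly values.
#'
#' @param value condition factor to place.
#' @param run baseline `run_output`.
#' @param pre_months months considered pre-spill.
#' @return percentile in (0, 100).
#' @export
condition_percentile <- function(value, run, pre_months = 1:3) {
  cf <- condition_factor(run)[pre_months, , drop = FALSE]
  100 * stats::ecdf(as.vector(cf))(value)
}

#' Per-capita consumption matrix by guild
#'
#' Consumed biomass per predator individual per day, predator guild by prey
#' guild, averaged over a month window; also returns the pelagic share of
#' fish-guild prey for each predator guild.
#'
#' @param run a `run_output`.
#' @param months month indices to average over.
#' @return list with `per_capita` (pred guild x prey guild, mg N per
#'   individual per day) and `pelagic_share` (per predator guild).
#' @export
consumption_matrix <- function(run, months = NULL) {
  if (is.null(months)) months <- seq_along(run$months)
  g <- run$groups
  cons <- apply(run$consumption[months, , , drop = FALSE], c(2, 3), sum)
  dimnames(cons) <- list(g$code, g$code)
  predN <- colMeans(run$pred_numbers[months, , drop = FALSE])
  days <- length(months) * 365 / 12
  glab <- g$guild
  cons_g <- rowsum(t(rowsum(cons, glab)), glab)      # prey guild x pred guild
  cons_g <- t(cons_g)                                # pred guild x prey guild
  predNg <- rowsum(predN, glab)[, 1]
  per_capita <- cons_g / pmax(predNg[rownames(cons_g)], 1e-300) / days
  # pelagic vs demersal share of forage-type prey per predator guild
  pel <- g$habitat == "pelagic"
  dem <- g$habitat %in% c("demersal", "benthic") & g$code != "DET"
  s_pel <- rowsum(rowSums(cons[, pel, drop = FALSE]), glab)[, 1]
  s_dem <- rowsum(rowSums(cons[, dem, drop = FALSE]), glab)[, 1]
  pel_share <- s_pel / pmax(s_pel + s_dem, 1e-300)
  list(per_capita = per_capita, pelagic_share = pel_share)
}

#' Ecosystem indicator series
#'
#' Biomass-weighted mean trophic level, Shannon diversity over group
#' biomass shares, the pelagic:demersal fish biomass ratio and the
#' piscivore:planktivore fish biomass ratio (piscivores are fish guilds
#' whose diet is predominantly fish).
#'
#' @param run a `run_output`.
#' @param web the `food_web` (for diet-based piscivory flags); defaults to
#'   flags derivable from the run's group table.
#' @return data.frame per month with `mean_tl`, `shannon`,
#'   `pelagic_demersal`, `piscivore_planktivore`.
#' @export
ecosystem_indicators <- function(run, web = NULL) {
  g <- run$groups
  B <- apply(run$biomass, c(1, 2), sum)       # month x group
  live <- g$type != "detritus"
  if (all(B[, live] <= 0)) stop("zero total biomass")
  tl <- g$trophic_level
  mean_tl <- rowSums(B[, live, drop = FALSE] *
                       rep(tl[live], each = nrow(B))) /
    rowSums(B[, live, drop = FALSE])
  p <- B[, live, drop = FALSE] / rowSums(B[, live, drop = FALSE])
  shannon <- -rowSums(ifelse(p > 0, p * log(p), 0))
  fish <- g$is_fish
  pel <- fish & g$habitat == "pelagic"
  dem <- fish & g$habitat != "pelagic"
  pd <- rowSums(B[, pel, drop = FALSE]) / pmax(rowSums(B[, dem, drop = FALSE]), 1e-300)
  pisc <- fish & g$trophic_level >= stats::median(g$trophic_level[fish])
  plank <- fish & !pisc
  pp <- rowSums(B[, pisc, drop = FALSE]) / pmax(rowSums(B[, plank, drop = FALSE]), 1e-300)
  data.frame(month = run$months, mean_tl = mean_tl, shannon = shannon,
             pelagic_demersal = pd, piscivore_planktivore = pp)
}

#' Annual catch ratio per fleet
#'
#' Whole-domain yearly catch of the impacted run relative to baseline.
#' Year-fleet cells with zero baseline catch return `NA` rather than an
#' error.
#'
#' @param impacted,baseline paired `run_output`s.
#' @return matrix year x fleet of catch ratios.
#' @export
catch_delta <- function(impacted, baseline) {
  check_paired(impacted, baseline)
  num <- impacted$catch
  den <- baseline$catch
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}
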