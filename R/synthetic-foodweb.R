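#' Default functional-group template
#'
#' Twelve functional groups: the eight fish guilds used for reporting
#' (snappers, groupers, sciaenids, elasmobranchs, large pelagic fish, small
#' pelagic fish, small demersal and reef fish, large demersal fish), two
#' plankton pools (phytoplankton, zooplankton), a benthic invertebrate forage
#' pool, and detritus. Columns give life-history parameters: number of age
#' classes, class width (years), maturity class, asymptotic weight (mg N),
#' von Bertalanffy growth, target total mortality (per year), domain biomass
#' (mg N), assimilation efficiency, maintenance rate, stock-recruit
#' steepness, habitat and depth preference, and fishing fleet membership.
#'
#' Turnover spans fast (forage, plankton) to slow (elasmobranchs, large
#' pelagics); guild biomasses form a plausible pyramid over the forage base.
#'
#' @return a `data.frame`, one row per functional group.
#' @export
guild_template <- function() {
  data.frame(
    code = c("SNP", "GRP", "SCI", "ELA", "LPF", "SPL", "SDR", "LDF",
             "PHY", "ZOO", "BEN", "DET"),
    name = c("snappers", "groupers", "sciaenids", "elasmobranchs",
             "large pelagic fish", "small pelagic fish",
             "small demersal and reef fish", "large demersal fish",
             "phytoplankton", "zooplankton", "benthic invertebrates",
             "detritus"),
    guild = c("snappers", "groupers", "sciaenids", "elasmobranchs",
              "large pelagic fish", "small pelagic fish",
              "small demersal and reef fish", "large demersal fish",
              "plankton", "plankton", "benthos", "detritus"),
    type = c(rep("fish", 8), "producer", "pool", "pool", "detritus"),
    habitat = c("demersal", "demersal", "demersal", "demersal", "pelagic",
                "pelagic", "demersal", "demersal",
                "pelagic", "pelagic", "benthic", "benthic"),
    benthic_prey = c(rep(FALSE, 8), FALSE, FALSE, TRUE, TRUE),
    n_age = c(rep(6L, 8), 1L, 1L, 1L, 1L),
    age_years = c(2, 4, 2, 5, 4, 1, 1, 3, 1, 1, 1, 1),
    maturity_class = c(3L, 3L, 3L, 4L, 3L, 2L, 2L, 3L, 1L, 1L, 1L, 1L),
    winf_mgN = c(2e4, 1e5, 1e4, 2e5, 3e5, 5e2, 3e2, 5e4, 1, 1, 1, 1),
    k_vb = c(0.25, 0.12, 0.3, 0.1, 0.15, 0.8, 0.9, 0.18, 0, 0, 0, 0),
    Z0 = c(0.55, 0.35, 0.6, 0.25, 0.3, 1.3, 1.5, 0.4, 0, 0, 0, 0),
    B0 = c(1.2e11, 8e10, 1.5e11, 6e10, 1.5e11, 1.2e12, 8e11, 1e11,
           6e12, 4e12, 6e12, 3e13),
    assim = c(rep(0.3, 8), NA, 0.35, 0.25, NA),
    maint = c(0.004, 0.003, 0.0045, 0.0025, 0.0035, 0.005, 0.005, 0.0035,
              NA, 0.02, 0.004, NA),
    steepness = c(0.7, 0.6, 0.7, 0.5, 0.55, 0.85, 0.85, 0.65,
                  NA, NA, NA, NA),
    pref_depth = c(80, 120, 60, 150, 800, 150, 50, 100,
                   NA, NA, NA, NA),
    diffusion = c(0.01, 0.005, 0.01, 0.02, 0.08, 0.04, 0.005, 0.01,
                  0, 0.02, 0, 0),
    fleet = c("reef", "reef", "reef", "demersal", "pelagic", "pelagic",
              "none", "demersal", "none", "none", "none", "none"),
    F0 = c(0.12, 0.06, 0.12, 0.04, 0.08, 0.1, 0, 0.08, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

# Default diet (availability) matrix over template codes; rows = predators.
default_diet <- function(codes) {
  D <- matrix(0, length(codes), length(codes), dimnames = list(codes, codes))
  D["SNP", c("SDR", "BEN", "SPL")] <- c(0.50, 0.25, 0.20)
  D["GRP", c("SDR", "SNP", "BEN", "SPL")] <- c(0.55, 0.10, 0.20, 0.10)
  D["SCI", c("BEN", "SDR", "SPL")] <- c(0.45, 0.35, 0.15)
  D["ELA", c("SDR", "SPL", "SCI", "BEN")] <- c(0.25, 0.15, 0.15, 0.30)
  D["LPF", c("SPL", "ZOO", "SDR")] <- c(0.75, 0.10, 0.05)
  D["SPL", c("ZOO", "PHY")] <- c(0.90, 0.05)
  D["SDR", c("BEN", "ZOO")] <- c(0.75, 0.20)
  D["LDF", c("BEN", "SDR", "SPL")] <- c(0.40, 0.40, 0.10)
  D["ZOO", "PHY"] <- 0.95
  D["BEN", c("DET", "PHY")] <- c(0.80, 0.15)
  D
}

#' Generate a parameterised food web
#'
#' Builds the functional-group set from a template: diet (availability)
#' matrix, trophic levels satisfying the recursive definition
#' `TL = 1 + weighted mean prey TL`, benthic diet fractions, habitat flags and
#' life-history rates, with small seeded lognormal jitter on rates so
#' replicate webs differ realistically while the structure is preserved.
#'
#' @param template a template `data.frame` as from [guild_template()]; must
#'   contain the eight fish guilds plus at least two plankton/forage pools and
#'   a detritus pool.
#' @param n_age_classes number of age classes for fish groups.
#' @param diet optional availability matrix (rows = predators, substochastic);
#'   defaults to the packaged matrix.
#' @param jitter_sd lognormal sd of the seeded rate jitter (0 disables).
#' @param seed integer seed.
#' @return A `food_web`: `groups` data.frame (with `trophic_level` and
#'   `benthic_frac`), `diet` matrix, and the benthic-prey flag vector.
#' @export
gen_food_web <- function(template = guild_template(), n_age_classes = 6,
                         diet = NULL, jitter_sd = 0.04, seed = 1) {
  need <- c("fish", "producer", "pool", "detritus")
  if (sum(template$type == "fish") < 8)
    stop("template must include the 8 fish guilds")
  if (sum(template$type %in% c("producer", "pool")) < 2 ||
      !any(template$type == "detritus"))
    stop("template must include >= 2 plankton/forage pools and detritus")
  set.seed(seed)
  g <- template
  g$is_fish <- g$type == "fish"
  g$n_age <- ifelse(g$is_fish, as.integer(n_age_classes), 1L)
  if (is.null(diet)) diet <- default_diet(g$code)
  if (any(diet < 0)) stop("diet availabilities must be non-negative")
  if (any(rowSums(diet) > 1 + 1e-9)) stop("diet row sums must be <= 1")
  # seeded jitter on rates (structure-preserving)
  jit <- function(x) x * exp(stats::rnorm(length(x), 0, jitter_sd))
  for (col in c("Z0", "B0", "maint", "winf_mgN"))
    g[[col]] <- ifelse(is.na(g[[col]]), g[[col]], jit(g[[col]]))
  g$trophic_level <- trophic_levels(diet, g$type)
  g$benthic_frac <- vapply(seq_len(nrow(g)), function(i)
    benthic_diet_fraction(diet[i, ], g$benthic_prey), 0)
  g$gape_min <- ifelse(g$is_fish, 3, NA)
  g$gape_max <- ifelse(g$is_fish, 3e5, NA)
  structure(list(groups = g, diet = diet, benthic_prey = g$benthic_prey,
                 n_groups = nrow(g), seed = seed),
            class = "food_web")
}

#' Trophic levels from a diet matrix
#'
#' Solves the recursive definition `TL_i = 1 + sum_j p_ij TL_j` with rows of
#' the diet matrix normalised to realised diet fractions; producers and
#' detritus are fixed at TL 1. A pure herbivore gets TL 2.
#'
#' @param diet availability/diet matrix (rows = predators).
#' @param type character vector of group types (`producer`/`detritus` rows are
#'   basal).
#' @return numeric vector of trophic levels.
#' @export
trophic_levels <- function(diet, type) {
  n <- nrow(diet)
  P <- diet / pmax(rowSums(diet), 1e-12)
  basal <- type %in% c("producer", "detritus") | rowSums(diet) == 0
  P[basal, ] <- 0
  solve(diag(n) - P, rep(1, n))
}

# Vertical distribution of each group over (water layers + sediment), per
# polygon. Rows sum to 1 over occupied layers. Static: vertical structure is
# separable from the horizontal dynamics.
layer_profiles <- function(web, geometry) {
  nl <- geometry$n_layers
  np <- geometry$n_polygons
  ng <- web$n_groups
  thick <- geometry$layer_thickness
  edges <- c(0, geometry$depth_cuts, Inf)
  prof <- array(0, c(ng, np, nl + 1))
  for (g in seq_len(ng)) {
    hab <- web$groups$habitat[g]
    code <- web$groups$code[g]
    for (p in seq_len(np)) {
      th <- thick[p, ]
      occ <- which(th > 0)
      bot <- max(occ)
      if (hab == "benthic") {
        if (code == "DET") {
          prof[g, p, nl + 1] <- 1
        } else {
          # epibenthos straddles the sediment-water interface
          prof[g, p, nl + 1] <- 0.55
          prof[g, p, bot] <- 0.45
        }
      } else if (hab == "demersal") {
        # near-bottom water plus time at the sediment-water interface,
        # where benthic prey are taken
        w <- numeric(nl + 1)
        w[bot] <- 0.5
        if (bot > 1) w[bot - 1] <- 0.2 else w[bot] <- 0.7
        w[nl + 1] <- 0.3
        prof[g, p, ] <- w / sum(w)
      } else {
        # pelagic: upper water column, thickness-weighted within a depth cap
        cap <- switch(code, LPF = 400, PHY = 20, ZOO = 20, 50)
        lim <- min(cap, geometry$polygons$bottom_depth[p])
        w <- pmax(pmin(edges[seq_len(nl) + 1], lim) -
                    pmin(edges[seq_len(nl)], lim), 0)
        if (sum(w) <= 0) w[1] <- 1
        prof[g, p, seq_len(nl)] <- w / sum(w)
      }
    }
  }
  dimnames(prof) <- list(web$groups$code, NULL, NULL)
  prof
}
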