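# Shared fixtures, built once per test session and cached.

.fx <- new.env(parent = emptyenv())

tiny_geometry <- function(n_polygons = 4, seed = 11) {
  key <- paste0("geo_", n_polygons, "_", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- gen_geometry(n_polygons = n_polygons,
                               depth_cuts = c(10, 50, 200),
                               grid_resolution = 0.5, seed = seed)
  .fx[[key]]
}

tiny_web <- function(seed = 7) {
  key <- paste0("web_", seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- gen_food_web(seed = seed)
  .fx[[key]]
}

tiny_state <- function(seed = 5) {
  key <- paste0("state_", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- init_state(tiny_web(), tiny_geometry(), seed = seed)
  .fx[[key]]
}

# The packaged demo system plus baseline and worst-case runs (10-year
# horizon). Expensive (a few minutes); built on first use.
demo_fixture <- function() {
  if (is.null(.fx$demo)) {
    inp <- demo_inputs(seed = 1)
    baseline <- run_scenario(build_scenario(
      scenario_config(oil_mortality = FALSE, oil_growth = FALSE,
                      label = "baseline"), inp))
    worst <- run_scenario(build_scenario(
      scenario_config(beta_reduction = 60), inp))
    .fx$demo <- list(inputs = inp, baseline = baseline, worst = worst)
  }
  .fx$demo
}

# Total nitrogen in a state, including the external migration pool.
total_nitrogen <- function(state) {
  sum(state$N * (state$sN + state$rN)) +
    sum(state$ext_N * (state$ext_sN + state$ext_rN))
}

# Signed flux sum of a step's flux record (biomass change it accounts for).
flux_signed_sum <- function(fx) {
  fx$recruit_in + fx$aging_net + fx$imm - fx$em - fx$pred_loss -
    fx$m1_loss - fx$catch + fx$growth - fx$spawn_out
}
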