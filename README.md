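# spillweb

Simulation pipeline for studying how a large subsurface oil spill propagates
through a marine ecosystem — from gridded polycyclic aromatic hydrocarbon
(PAH) concentration fields, through organism-level toxicology, to
population, food-web, fishery and recovery responses. It is aimed at
ecosystem modellers and ecotoxicologists who want a self-contained,
desk-scale analogue of end-to-end spill assessments: every input (geometry,
oil fields, food web, closure schedules, larval losses) is generated by the
package, so the full analysis chain runs and is testable without any
external data.

## The model in brief

Biomass `B` (mg N) of each age class of functional group *i*, per polygon
and layer, evolves as

    dB_i/dt = [R_i + T_imm,i - T_em,i - M1_i - sum_j P_ij - F_i] + g_oil [G_i,s + G_i,r]

with recruitment/aging `R`, migration `T`, predation `P_ij` (multi-prey
Holling type II with gape limitation and vertical co-occurrence), fishing
`F`, growth in structural and reserve nitrogen `G_s, G_r`, and non-predation
mortality `M1 = m_l + m_q B + m_oil`. The oil terms come from hockey-stick
dose-responses on accumulated body burden `phi`:

    m_t = alpha ln(K phi / beta) / omega,   g_t = gamma ln(K phi / delta) / omega
    phi_t = phi_{t-1} e^{-rho} + mu O_t

zero below the thresholds, with `alpha = 0.2885`, `beta = 907.43` ppb,
`gamma = 0.0531`, `delta = 28.42` ppb, `omega = 15` d, depuration
`rho = 0.2424` d⁻¹ (99% clearance in 20 days), uptake `mu = 1` (benthic) or
`0.1` (pelagic), and sediment concentration factor `K` (default 1000).
Mortality and growth modifiers are convex combinations of pelagic and
benthic effects weighted by each group's benthic diet fraction. Scenario
machinery runs a 4×4 sensitivity grid over reductions of `K`
(1000/800/600/400) and `beta` (907/726/544/363 ppb), plus closures-only and
recruitment-only runs, against one shared no-oil baseline.

## Worked example

```r
library(spillweb)

inp   <- demo_inputs(seed = 1)        # builds and burns in the demo system (~2 min)
base  <- run_scenario(build_scenario(
           scenario_config(oil_mortality = FALSE, oil_growth = FALSE), inp))
worst <- run_scenario(build_scenario(
           scenario_config(beta_reduction = 60), inp))   # "K1000 b363"

cmp <- relative_biomass(worst, base)  # heavily impacted polygons
biomass_minimum(cmp, spill_day = worst$spill_day)
```

prints, for the worst case (guild biomass relative to the no-oil baseline in
the most affected polygons):

```
                         guild min_ratio month_of_min
                 elasmobranchs     0.194         5.38
                      groupers     0.349         5.38
           large demersal fish     0.159         5.38
            large pelagic fish     0.222         6.38
                     sciaenids     0.123         5.38
  small demersal and reef fish     0.032         5.38
            small pelagic fish     0.555         5.38
                      snappers     0.300         5.38
```

The benthic/reef forage base (small demersal and reef fish) takes the
deepest hit, minima fall 5-6 months after the spill, and impact depth
tracks each guild's reliance on benthic prey (Spearman rank correlation
-0.90). `recovery_time(cmp, ...)` shows the fast-turnover guilds returning
to 99% of baseline within 1.7-3.3 years while the slow-growing guilds have
not recovered within the 10-year demo horizon; `ecosystem_indicators()`
shows diversity and mean trophic level dipping while the pelagic:demersal
ratio rises.

The numbered scripts under `analysis/` run the full study: input
generation, single-factor (closures, recruitment) runs, the 16-run
sensitivity grid, and the impact analysis, writing tables under `results/`.

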