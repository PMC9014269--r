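# cropideo

Simulation-based ideotyping for crop–weed competition, built around pea
(*Pisum sativum* L.) and annual arable weed floras.

Current pea varieties compete poorly against weeds, and field screening of
candidate varieties cannot hold a weed-free control constant. `cropideo`
attacks the problem *in silico*, for breeders and cropping-system
agronomists: it parameterizes varieties from individual-plant measurements,
invents plausible new ones, grows them in a virtual field against weeds
under thousands of candidate management plans, and mines the results for
the parameter and management rules that drive yield, weed control and
weed-borne biodiversity.

## What the package computes

1. **Variety parameterization from garden plots.** Individual isolated
   plants, grown with and without shading nets, are measured at ~5 BBCH
   stages. Per stage, potential morphology follows power-law allometry —
   `height = HM · B^b_HM` and `width = WM · B^b_WM` against above-ground
   biomass `B` — plus the ratios `SLA` (leaf area / leaf biomass) and `LBR`
   (leaf biomass / B) and a two-parameter cumulative leaf-area profile
   `F(h) = 1 / (1 + ((RLH(1−h))/((1−RLH)h))^{b_RLH})` along relative height.
   Shade response is exponential, `X = X₀ · exp(mu_X · s)`, in the shading
   intensity `s = 1 − PAR_shaded / PAR_unshaded`. Fits are interpolated to
   the 11 BBCH stages (emergence 0 → full maturity 10).
2. **Virtual varieties.** The 7 reference varieties define per-parameter
   ranges (extended by 10%, capped at biological limits) and a Pearson
   correlation matrix; new varieties are drawn by Latin hypercube sampling
   with Iman–Conover rank-correlation induction, so marginals stay
   stratified and trait correlations stay biological.
3. **Cropping systems.** Nine preset situations (reference, all-levers,
   organic, no-till, 2/4/6-crop rotations, two contrasting weed seed banks)
   each receive an LHS-stratified plan of systems: rotation, sowing
   date/density/interrow, tillage, herbicides, mechanical weeding, residue
   handling — all under codified agronomic constraints (sowing windows,
   tillage before sowing, full maturation feasibility).
4. **The virtual field.** A daily individual-based simulator: seed-bank
   germination `F(tt) = 1 − exp(−ln2 ((tt−g0)/(g50−g0))^{gb})` gated by
   moisture and depth, pre-emergent shoot growth with `ln(mm)`-depth
   mortality, a 3-D cylinder-plant canopy with Beer–Lambert light partition
   on a torus grid, temperature-ramped light-driven growth, thermal-time
   phenology, weed seed return, and all management operations. Every system
   runs twice with matched random streams — weedy and weed-free — so crop
   yield loss is `100 · (Y_weedfree − Y_weedy) / Y_weedfree`.
5. **Indicators and trees.** Potential yield, weed-infested yield, yield
   loss, field infestation, weed species richness, bee food and herbicide
   intensity, min–max rescaled to [0, 1] (harmfulness flipped into
   "control" indicators); analyzed with multivariate regression trees
   (surrogate splits, 10-fold cross-validated cost-complexity pruning),
   variable importance (VIP), partial R² per predictor class, probability
   of increase, and min–max best-branch ideotype rules matched back to
   concrete varieties.

## Worked example

```r
library(cropideo)

vs   <- pea_reference_varieties()
env  <- build_envelope(vs)
pool <- c(vs, generate_virtual_varieties(env, 10, seed = 1))

plan    <- build_plan(situation_presets()$reference, 16, pool, seed = 3)
weeds   <- gen_weed_pool("complete", seed = 1)
bank    <- new_seed_bank(weeds)
weather <- gen_weather(6, seed = 7)

pr <- simulate_pair(plan[[1]], pool, weeds, weather, bank,
                    seed = 9, nYears = 3)
subset(pr$weedy$years, crop == "pea",
       c(yield_t_ha, weedBiomass_t_ha, speciesRichness))
#>   yield_t_ha weedBiomass_t_ha speciesRichness
#> 3  0.6263294         11.32973              24
subset(pr$weedfree$years, crop == "pea", yield_t_ha)
#>   yield_t_ha
#> 3   3.789908
```

The pea year of this system yields 3.79 t/ha weed-free but only 0.63 t/ha
with weeds — an 83% yield loss under 11.3 t/ha of weed biomass from 24
emerged species, a heavily infested unsprayed system. `run_pipeline(pipeline_config())` chains the whole study
(varieties → plans → paired simulations → indicators → trees) and writes
the class-wise partial-R² grid, best-branch rule listings and per-predictor
importance tables to CSV; reruns with the same master seed are
byte-identical.

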