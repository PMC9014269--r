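---
title: "Models and methods behind cropideo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cropideo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cropideo` is a desk-scale pipeline for designing crop ideotypes against
weeds. This vignette explains the models it implements, the parameters
that matter, what the synthetic-data generators do and do not emulate,
and the numerical and design choices a maintainer should know about.

## The variety parameter model

A variety is a vector of biological parameters organized around the
annual life cycle:

* **Germination.** After a moisture trigger (sowing into a moist seedbed,
  or the first post-sowing rain), the cumulative fraction of non-dormant
  seeds germinated after thermal time $tt$ is
  $F(tt) = 1 - \exp\!\big(-\ln 2\,((tt-g_0)/(g_{50}-g_0))^{g_b}\big)$ for
  $tt > g_0$, so $F(g_0)=0$ and $F(g_{50})=0.5$ by construction. `g0` and
  `g50` are thermal times (°C·d) to first and 50% germination; `gb ≥ 1`
  shapes how abrupt the flush is. Multiplicative reductions apply for
  darkness (buried seeds), surface exposure, and per-cm depth.
* **Pre-emergence.** The heterotrophic shoot elongates with Hill-type
  kinetics $S(tt) = L_{shoot}\, tt^{r_b}/(tt^{r_b}+r_{50}^{r_b})$; the
  seedling emerges when $S$ reaches its seed depth and can never emerge
  from below $L_{shoot}$. One mortality draw at emergence follows
  $m = \mathrm{clamp}(m_0 + \gamma \ln(\mathrm{depth_{mm}}), 0, 1)$.
  Because $\gamma \approx 0.34$ for pea, emergence from below ~1.5 cm is
  negligible; the management sampler therefore drills shallow (0.3–1.2
  cm).
* **Morphology.** At each of 11 BBCH stages (0 = emergence, 10 = full
  maturity): specific leaf area `SLA` (cm²/g), leaf biomass ratio `LBR`
  (g/g), the allometric pairs `HM`/`b_HM` and `WM`/`b_WM` giving height
  and width as power laws of above-ground biomass (capped at
  `max_height`, `max_width`), and the leaf-profile pair `RLH`/`b_RLH`.
  The cumulative leaf-area fraction below relative height $h$ is
  $F(h) = \big(1 + ((RLH(1-h))/((1-RLH)h))^{b_{RLH}}\big)^{-1}$ —
  logistic in $\mathrm{logit}(h)$, with median exactly `RLH` and
  uniformity at `RLH = 0.5, b_RLH = 1`.
* **Shade response.** Each morphology parameter X shifts under shading
  intensity $s = 1 - \mathrm{PAR_{shaded}}/\mathrm{PAR_{unshaded}}$ as
  $X = X_0 e^{\mu_X s}$. We adopt the positive sign convention — $\mu >
  0$ means the trait increases under shading, so a shade-avoiding
  variety has $\mu_{HM} > 0$ and rules like "large $\mu_{HM}$ is good"
  read naturally; the opposite convention is also in circulation for
  this law, so the sign is switchable via
  `options(cropideo.shade_sign = -1)`.
* **Phenology, growth, reproduction.** Thermal time above `baseTempDev`
  maps piecewise-linearly onto BBCH stages: 0–4 spans
  `PeaFloweringTT`, 4–8 the flowering window `TTflo`, 8–10 the
  maturation window `TTmat`. Daily biomass gain is radiation-use
  efficiency times absorbed PAR times a temperature ramp (0 below
  `tPhoto1`, 1 above `tPhoto2`). At harvest a crop yields
  `harvestIndex · B`; a mature weed returns
  `seedAllocation · B / seedMass` seeds to the soil surface.

The seven reference varieties set published per-variety measurements
(seed mass, harvest index, maximum height/width, seasonality, leaf type)
exactly; all other entries are placed inside the observed inter-variety
ranges, spread so varieties genuinely differ. Parameters with no
variety-specific information (e.g. `baseWP`, `reductionSurface`,
`gamma`) are identical across varieties and stay frozen in virtual ones.
Winter varieties' phenophases were chosen so that every variety can
complete its cycle within one harvest-to-harvest year under the
package's climate — a feasibility the management sampler enforces
anyway, so longer settings would merely compress every variety onto the
earliest sowing date.

## Synthetic garden plots

`gen_garden_plot()` emulates the isolated-plant shading-net experiment:
at each sampled stage and net level it draws per-plant biomass
log-uniformly between 0.4 and 2.5 times an exponential-in-stage typical
value — the large between-individual spread of open-grown plants, which
is also the leverage that identifies the allometric exponents at the
design's noise level — scaled so plants stay below their dimension caps
(a binding cap would make the exponents unidentifiable), and derives all
measurements from the laws above, with
multiplicative lognormal measurement error of coefficient of variation
`noiseCV`. It does **not** emulate: soil texture effects, within-plant
measurement correlation, camera segmentation error structure, or
mortality in the plots. Passing recovery tests therefore demonstrate
estimator correctness, not robustness to real measurement pathologies.

Estimation mirrors the generating laws: log–log OLS with Duan smearing
retransformation for the power laws (exact on noise-free data, unbiased
under lognormal error); ratio-of-sums estimators for `SLA` and `LBR`;
Levenberg–Marquardt least squares for the leaf profile, initialized by
the exact logit-scale OLS; shade coefficients by regressing
$\log(X_i/X_0)$ on $s_i$ through the origin with $X_0$ fixed at the
unshaded fit (co-estimation is available but increases collinearity).
Stage fits are expanded to the 11 BBCH stages by an *interpolating*
piecewise-linear profile, clamped outside the sampled stages: with only
five sampling stages a smoothing bandwidth would contradict the
requirement that the profile honor each stage fit (noise-free fits have
zero standard error); `smooth = TRUE` switches to a loess(degree = 1)
smooth for denser designs.

## Virtual varieties

`build_envelope()` computes per-parameter ranges and the inter-variety
Pearson correlation matrix over the flattened parameter vectors, working
in transformed coordinates where the ordered pairs (`g0`,`g50`) and
(`tPhoto1`,`tPhoto2`) become (lower, positive gap) — order constraints
then hold for any joint draw, with rejection sampling unnecessary. The
sampling range extends each bound outward by 10% of its magnitude,
capped into hard biological limits ([0,1] for proportions, (0,1) for
`RLH`, ≥1 for the shape parameters). For negative bounds a literal
0.9·min/1.1·max rule would *narrow* the range; outward extension by
10% of |bound| reduces to the same rule for positive parameters and is
what "extend the range" means.

With 7 varieties the correlation matrix is rank-deficient, so it is
repaired to the nearest positive semi-definite matrix (eigenvalue
clipping at 1e-8, rescaled to unit diagonal) before its Cholesky factor
constrains the draw. `lhs_correlated()` performs Iman–Conover induction:
van der Waerden scores receive the target correlation through the
Cholesky factor (with empirical de-correlation of the raw scores when
n sufficiently exceeds the dimension), and each Latin-hypercube column
is reordered to match the score ranks — marginal stratification is
preserved exactly and the induced rank correlations are invariant to
monotone reparameterization. Virtual varieties are labelled spring or
winter by their sampled flowering thermal time (threshold 1000 °C·d):
in the simulator the label itself has no mechanism, so the cycle length
is the honest classifier.

## Cropping systems and "agronomic logic"

The rule table behind `sample_crop_techniques()` codifies: per-crop
sowing windows on a crop-year clock starting 1 August (pea 1 Oct–15 Apr,
winter wheat autumn-only, oilseed rape late August, maize and sunflower
in spring); false-seed-bed tillage and residue shredding only in the
fallow before sowing, with a final shallow seedbed pass the day before
drilling; herbicides and mechanical weeding timed relative to sowing;
harvest at the date where the climatological thermal sum exceeds the
variety's full requirement plus a 250 °C·d buffer against interannual
variability. A drawn sowing date that cannot mature is clamped earlier;
a variety that cannot mature anywhere in the window is a hard constraint
error. Continuous technique variables are stratified across a plan's
systems by one Latin hypercube; categorical choices (rotation order,
variety, residue handling) are uniform draws — how to stratify
categoricals is genuinely open, and uniform sampling keeps the audit
interpretable. `audit_plan_correlations()` verifies the decorrelation
(median |r| among technique variables is small; rotation variables are
intercorrelated by construction of the rotation rules).

## The virtual field

One field (default 20 m²) is a torus — no edge effects at this scale.
Plants are cylinders: leaf area spreads over the crown-disc footprint on
a horizontal grid (default 0.5 m cells) and vertically by the leaf
profile over layers (default 2 cm, capped at 24 layers with
proportionally coarser slabs for tall canopies). Light attenuates down
each column by Beer–Lambert (extinction `k = 0.7`) and each element's
absorption is shared by leaf area. A plant's shading intensity is read
at its median leaf height from *other* plants' leaf area above —
self-shading is excluded because $s$ mimics the shading-net experiment,
which shades from neighbors and above. The daily loop and light kernel
are compiled; an independent plain-R integrator in the test suite is the
correctness oracle.

Simulation covers the rotation span (first scheduled operation minus a
60-day lead-in through the last harvest): the rotation is a
harvest-to-harvest schedule, and months before any management exists are
outside the study. Cross-year conflicts — a late harvest overlapping the
next crop-year's fallow — drop the overlapped fallow tillage and push
later operations past the harvest.

Free constants for which the mechanisms above fix no value, all exposed
in `sim_config()` with defaults chosen once as field-plausible: RUE = 2
g/MJ absorbed PAR, pre-emergence mortality intercept `m0 = 0.05`,
herbicide stage decay 0.15 per BBCH stage, mechanical-weeding kill
0.8·exp(−B/2 g) with 3% crop damage per pass, residue-layer emergence
factor 0.6 for 120 days, emerged-weed cap 30 plants/m² (a computational
capacity limit), moisture = 3 mm rain over 7 days. Water acts only on
germination; nitrogen, frost and disease are not modelled; winter and
spring types differ only through parameters and sowing windows.

All stochastic draws go through named, independently seeded streams
(weed placement/efficacy vs crop placement/damage), so zeroing the
initial weed seed bank leaves every crop-related draw untouched — the
weedy and weed-free runs of a pair are exactly matched, and weed-free
yield dominates weedy yield system-by-system. Fractional expected counts
are materialized deterministically (floor plus carry), which also makes
the seed-bank audit exact: initial − germinated + returned = final, to
rounding.

## Indicators and rescaling

Raw indicators per (situation, system, year, weather repetition):
potential yield (weed-free), weed-infested yield, yield loss (may be
negative), field infestation = weed biomass at crop harvest, species
richness = weed species with ≥1 emerged plant in the crop year, bee food
= attractiveness-weighted weed biomass summed over each species'
flowering window (a proxy with the correct direction of meaning), and
herbicide intensity = applications per year (a treatment-frequency
proxy). Min–max rescaling to [0,1] runs over
the *entire* table — all situations, systems, years, repetitions — and
flips harmfulness indicators into "control" twins (`yieldLossControl`,
`herbicideUseReduction` = 1 at zero use). Rescaling is idempotent and
order-preserving; constant columns map to 0.5 with a warning. The
rotation scale averages all crop years, so rotation-scale yield includes
the non-pea crops.

## Multivariate regression trees

`grow_tree()` minimizes the pooled within-child sum of squares over the
response columns (rescaled indicators are already commensurable, so
standardization is off by default and available as a config). Split
search is exact over midpoints; categorical predictors are scanned along
the ordering of category mean responses; ties break toward the lower
predictor index then lower threshold, making builds deterministic. Up to
20 surrogates per split are ranked by raw agreement and kept only while
they beat the go-with-majority baseline; rows missing the primary
predictor route by the best surrogate. Pruning follows cost-complexity
with 10-fold cross-validation on the relative (cp) scale, testing the
geometric means of the weakest-link alphas plus both endpoints (the full
tree and the root — omitting the root biases the choice toward spurious
structure on pure noise), and selects the CV-error minimum (not the
1-SE rule). The reported R² is cross-validated.

Importance: a predictor's VIP accumulates each split's SS-improvement
when primary, and agreement-weighted improvement when surrogate (raw
agreement — the simplest defensible weighting; an adjusted-agreement
variant as in rpart would discount surrogates more aggressively). Relative VIPs sum to 1; partial R² =
relVIP × cvR²; class partial R² sums members (situation, pea parameters,
pea techniques, other-crop techniques). The probability of increase is
the node-size-weighted share of nodes, among those where the predictor
splits (primary or surrogate), whose higher-predictor child has the
higher mean response — the normalization over contributing nodes is our
normalization choice. Best
branches order leaves by the minimum of their indicator means
(multivariate) or the mean (univariate); the top branch then satisfies
$\min_i T_{bi} > \max_{b'} \min_i T_{b'i}$ against every other leaf.
Branch parameter rules (prefix `pea.`) match varieties by direct
evaluation — scalar names, early/mid/late stage summaries (BBCH windows
[0,4], [4,8], [8,10]), or explicit stage entries; technique and
situation rules are ignored for matching.

## Problem sizes and limitations

The default desk profile (2 situations × 20 systems × 3 years × 2
weather repetitions, paired) runs in minutes on one CPU and is the scale
at which the test suite and the acceptance script exercise the full
pipeline; the full study shape (9 × 400 × 12 × 5) uses the same
configuration object and is cluster-scale. Headline numbers of any
specific field study are not reproducible at desk scale — the package's
claims are the property-based ones its tests assert: exact generative
laws, exact recovery, LHS stratification and correlation control,
constraint satisfaction, conservation, paired dominance, and
oracle-exact tree mechanics. Known limitations: the weather generator is
a sinusoid-plus-noise stand-in; weed species parameters are drawn from
envelopes rather than measured; bee food and herbicide intensity are
directional proxies; post-emergence water and nitrogen competition are
absent; and the light model's horizontal resolution (0.5 m) is coarser
than a real row structure.
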