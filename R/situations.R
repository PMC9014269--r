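# Situations: preset cropping-context configurations that stratify the
# simulation plan (allowed crops, permitted weed-control levers, fertilizer
# type and initial weed species pool).

#' Situation specification
#'
#' @param name situation name.
#' @param crops allowed crops, subset of
#'   `c("pea", "winter_wheat", "WOSR", "barley", "sunflower", "maize")`.
#' @param tillageAllowed,herbicidesAllowed,mechanicalWeedingAllowed logical.
#' @param fertilizerType `"mineral"` or `"organic"`.
#' @param weedPoolKind passed to [gen_weed_pool()].
#' @return object of class `cropideo_situation`.
#' @export
situation_spec <- function(name, crops, tillageAllowed = TRUE,
                           herbicidesAllowed = TRUE,
                           mechanicalWeedingAllowed = FALSE,
                           fertilizerType = c("mineral", "organic"),
                           weedPoolKind = "complete") {
  all_crops <- c("pea", "winter_wheat", "WOSR", "barley", "sunflower",
                 "maize")
  stopifnot(all(crops %in% all_crops), "pea" %in% crops)
  obj <- list(name = name, crops = crops, tillageAllowed = tillageAllowed,
              herbicidesAllowed = herbicidesAllowed,
              mechanicalWeedingAllowed = mechanicalWeedingAllowed,
              fertilizerType = match.arg(fertilizerType),
              weedPoolKind = weedPoolKind)
  class(obj) <- "cropideo_situation"
  obj
}

#' The nine preset situations
#'
#' A reference pea / winter wheat / winter oilseed rape system with tillage
#' and herbicides; three management variants (all levers, organic without
#' herbicides, no-till); three rotation-length variants (2, 4, 6 crops);
#' and two initial weed seed-bank variants (6 harmful weeds, 6 harmful
#' bee-food dicots).
#'
#' @return named list of 9 `cropideo_situation` objects.
#' @export
situation_presets <- function() {
  ref <- c("pea", "winter_wheat", "WOSR")
  list(
    reference = situation_spec("reference", ref),
    complete = situation_spec("complete", ref,
                              mechanicalWeedingAllowed = TRUE),
    organic = situation_spec("organic", ref, herbicidesAllowed = FALSE,
                             mechanicalWeedingAllowed = TRUE,
                             fertilizerType = "organic"),
    no_till = situation_spec("no_till", ref, tillageAllowed = FALSE),
    rotation2 = situation_spec("rotation2", c("pea", "winter_wheat")),
    rotation4 = situation_spec("rotation4",
                               c("pea", "winter_wheat", "WOSR", "barley")),
    rotation6 = situation_spec("rotation6",
                               c("pea", "winter_wheat", "WOSR", "barley",
                                 "sunflower", "maize")),
    harmful = situation_spec("harmful", ref, weedPoolKind = "harmful"),
    harmful_bee = situation_spec("harmful_bee", ref,
                                 weedPoolKind = "bee_food"))
}

# Crop-year clock: day 0 = 1 August before harvest year; all operation
# dates are offsets on this clock (0..~450, summer crops harvest past 365).
CROP_YEAR_START_DOY <- 213L

# Per-crop agronomic rule table: sowing window (crop-year offsets), sowing
# density (seeds or plants per m2) and interrow (cm) envelopes, thermal
# time from sowing to emergence onset used by the maturation check.
.crop_rules <- function() {
  data.frame(
    crop = c("pea", "winter_wheat", "WOSR", "barley", "sunflower", "maize"),
    sowMin = c(61, 61, 19, 61, 243, 257),
    sowMax = c(257, 136, 50, 257, 287, 303),
    densMin = c(25, 150, 30, 150, 5, 7),
    densMax = c(115, 350, 70, 350, 10, 12),
    interMin = c(4, 10, 17, 10, 40, 40),
    interMax = c(52, 20, 60, 20, 80, 80),
    stringsAsFactors = FALSE)
}

# Climatological cumulative thermal time (base 0) on the crop-year clock.
.climatological_tt <- function(climate = default_climate()) {
  offs <- 0:460
  doy <- (CROP_YEAR_START_DOY - 1 + offs) %% 365 + 1
  cumsum(pmax(seasonal_temperature(doy, climate), 0))
}

# Thermal-time requirement from sowing to full maturity for a variety:
# germination + pre-emergence (proxy) + the three phenophases.
.tt_requirement <- function(variety) {
  variety$g50 + variety$r50 + variety$PeaFloweringTT + variety$TTflo +
    variety$TTmat
}

#' Generic parameter sets for the non-pea crops
#'
#' Fixed, plausible parameter sets for winter wheat, winter oilseed rape,
#' barley, sunflower and maize, used for the rotation years around pea.
#' Management of these crops varies across systems; their parameters do
#' not.
#'
#' @return named list of `cropideo_variety`.
#' @export
crop_presets <- function() {
  base <- pea_reference_varieties()$Kayanne
  mk <- function(name, seasonality, maxh, maxw, HI, seedMass, fTT, TTflo,
                 TTmat, SLAa, HMa, monocot) {
    v <- base
    v$name <- name
    v$seasonality <- seasonality
    v$leafType <- "leafy"
    v$max_height <- maxh; v$max_width <- maxw
    v$harvestIndex <- HI; v$seedMass <- seedMass
    v$PeaFloweringTT <- fTT; v$TTflo <- TTflo; v$TTmat <- TTmat
    v$stages$SLA <- stage_profile(SLAa[1], SLAa[2], SLAa[3])
    v$stages$HM <- stage_profile(HMa[1], HMa[2], HMa[3])
    v$monocot <- monocot
    validate_variety(v)
    v
  }
  list(
    winter_wheat = mk("winter_wheat", "winter_hr", 95, 25, 0.48, 45,
                      1450, 350, 600, c(220, 180, 110), c(20, 25, 40), TRUE),
    WOSR = mk("WOSR", "winter_hr", 160, 60, 0.30, 4.5,
              1500, 500, 650, c(200, 170, 100), c(25, 30, 45), FALSE),
    barley = mk("barley", "winter_hr", 85, 25, 0.50, 42,
                1250, 320, 550, c(230, 190, 120), c(18, 22, 35), TRUE),
    sunflower = mk("sunflower", "spring", 180, 60, 0.35, 55,
                   900, 350, 500, c(180, 150, 90), c(30, 35, 50), FALSE),
    maize = mk("maize", "spring", 250, 70, 0.50, 280,
               950, 300, 550, c(200, 160, 95), c(35, 40, 55), TRUE))
}
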