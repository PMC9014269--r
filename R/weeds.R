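# 26 frequent annual arable weed species (EPPO-style codes), with morphology
# group and whether the species is attractive to bees when flowering.
.weed_catalog <- function() {
  data.frame(
    name = c("ALOMY", "AVEFA", "POAAN", "LOLMU", "ECHCG", "SETVI", "BROST",
             "CHEAL", "POLAV", "POLPE", "FALCO", "STEME", "GALAP", "MATIN",
             "CAPBP", "SENVU", "SOLNI", "AMARE", "GERDI", "VERHE", "VIOAR",
             "FUMOF", "PAPRH", "SINAR", "CENCY", "MERAN"),
    monocot = c(rep(TRUE, 7), rep(FALSE, 19)),
    bee = c(rep(FALSE, 7),
            FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
            FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
            TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

# Sampling envelopes for weed parameters; where a published cross-species
# range exists it is used, otherwise a field-realistic synthetic envelope
# (notably max_height, see package docs) is substituted.
.weed_envelopes <- function() {
  list(
    g0 = c(6.4, 33.3), g50gap = c(5, 20), gb = c(1.5, 3.5),
    nonDormantMin = c(0.2, 0.9), baseWP = c(-3, -1),
    darknessReduction = c(0.40, 1.00), reductionSurface = c(0.3, 0.8),
    reductionDepth = c(0.0005, 0.002),
    shootDiameter = c(0.44, 2.20), shootLength = c(50, 300),
    rootLength = c(20, 100), r50 = c(50, 150), rb = c(1.24, 1.52),
    gamma = c(0.41, 0.58), C0surface = c(10, 40),
    LA0 = c(0.05, 1), se_LA = c(0.02, 0.5), RGR = c(0.005, 0.03),
    max_height = c(20, 150), max_width = c(10, 80),
    Emax = c(191, 363), rateWidth = c(2, 8), rateDepth = c(5, 20),
    rateCyl = c(0.05, 0.3), soilPen = c(0.5, 1),
    baseTempDev = c(0, 6), FloweringTT = c(434, 1600),
    TTflo = c(200, 800), TTmat = c(300, 700),
    tPhoto1 = c(0, 3), tPhoto2gap = c(8, 27),
    seedMass = c(0.5, 8), seedAllocation = c(0.05, 0.4),
    SLA = c(100, 350), LBR_e = c(0.6, 0.9), LBR_l = c(0.1, 0.6),
    HM = c(5, 40), b_HM = c(0.1, 0.5), WM = c(1, 40), b_WM = c(0.05, 0.75),
    RLH = c(0.3, 0.7), b_RLH = c(1.28, 5),
    mu_SLA = c(0, 0.8), mu_LBR = c(-0.6, 0.8), mu_HM = c(0, 1.77),
    mu_WM = c(-0.5, 0.5), mu_RLH = c(-0.2, 0.2))
}

.runif_env <- function(env, nm) runif(1, env[[nm]][1], env[[nm]][2])

# Build one weed species parameter set from the envelope draws.
.gen_weed_species <- function(nm, monocot, bee, env) {
  g0 <- .runif_env(env, "g0")
  tp1 <- .runif_env(env, "tPhoto1")
  scalars <- list(
    nonDormantMin = .runif_env(env, "nonDormantMin"),
    baseWP = .runif_env(env, "baseWP"), g0 = g0,
    g50 = g0 + .runif_env(env, "g50gap"), gb = .runif_env(env, "gb"),
    darknessReduction = .runif_env(env, "darknessReduction"),
    reductionSurface = .runif_env(env, "reductionSurface"),
    reductionDepth = .runif_env(env, "reductionDepth"),
    shootDiameter = .runif_env(env, "shootDiameter"),
    shootLength = .runif_env(env, "shootLength"),
    rootLength = .runif_env(env, "rootLength"),
    r50 = .runif_env(env, "r50"), rb = .runif_env(env, "rb"),
    gamma = .runif_env(env, "gamma"), C0surface = .runif_env(env, "C0surface"),
    LA0 = .runif_env(env, "LA0"), se_LA = .runif_env(env, "se_LA"),
    RGR = .runif_env(env, "RGR"),
    max_height = .runif_env(env, "max_height"),
    max_width = .runif_env(env, "max_width"),
    Emax = .runif_env(env, "Emax"), rateWidth = .runif_env(env, "rateWidth"),
    rateDepth = .runif_env(env, "rateDepth"),
    rateCyl = .runif_env(env, "rateCyl"), soilPen = .runif_env(env, "soilPen"),
    baseTempDev = .runif_env(env, "baseTempDev"),
    PeaFloweringTT = .runif_env(env, "FloweringTT"),
    TTflo = .runif_env(env, "TTflo"), TTmat = .runif_env(env, "TTmat"),
    tPhoto1 = tp1, tPhoto2 = tp1 + .runif_env(env, "tPhoto2gap"),
    harvestIndex = 0, seedMass = .runif_env(env, "seedMass"))
  anchor <- function(nm2) sort(runif(3, env[[nm2]][1], env[[nm2]][2]))
  stages <- data.frame(stage = 0:10)
  sla <- anchor("SLA")
  stages$SLA <- stage_profile(sla[3], sla[2], sla[1])
  stages$LBR <- stage_profile(.runif_env(env, "LBR_e"),
                              .runif_env(env, "LBR_e"),
                              .runif_env(env, "LBR_l"))
  hm <- anchor("HM")
  stages$HM <- stage_profile(hm[1], hm[2], hm[3])
  for (p in c("b_HM", "b_WM", "RLH", "b_RLH", "mu_SLA", "mu_LBR", "mu_HM",
              "mu_WM", "mu_RLH")) {
    a <- runif(3, env[[p]][1], env[[p]][2])
    stages[[p]] <- stage_profile(a[1], a[2], a[3])
  }
  wm <- anchor("WM")
  stages$WM <- stage_profile(wm[3], wm[2], wm[1])
  stages <- stages[, c("stage", STAGE_PARAMS)]
  variety_parameter_set(
    nm, "spring", "leafy", scalars, stages,
    seedAllocation = .runif_env(env, "seedAllocation"),
    beeAttractiveness = if (bee) runif(1, 0.5, 1.5) else 0,
    monocot = monocot)
}

#' Generate a weed species pool
#'
#' Weed species share the crop parameter schema (the life cycle treats crops
#' and weeds identically) plus reproduction fields: `seedAllocation` (g seed
#' per g above-ground biomass), `beeAttractiveness` and a monocot flag.
#' Three pools are available: the complete pool of 26 contrasting annual
#' species; the 6 most harmful species (highest competitive-trait score:
#' standardized max height, mid-stage height shade response, relative growth
#' rate and root extension); and 6 harmful bee-attractive dicots.
#'
#' @param kind one of `"complete"`, `"harmful"`, `"bee_food"`.
#' @param seed integer seed (species parameter draws are deterministic
#'   under it).
#' @return named list of `cropideo_variety` weed species with an attribute
#'   `kind`.
#' @export
gen_weed_pool <- function(kind = c("complete", "harmful", "bee_food"),
                          seed = 1) {
  kind <- match.arg(kind)
  cat26 <- .weed_catalog()
  env <- .weed_envelopes()
  pool <- with_stream(seed, "weedpool", {
    out <- list()
    for (i in seq_len(nrow(cat26)))
      out[[cat26$name[i]]] <- .gen_weed_species(
        cat26$name[i], cat26$monocot[i], cat26$bee[i], env)
    out
  })
  score <- vapply(pool, function(w) {
    sm <- stage_summary(w$stages$mu_HM)
    w$max_height / 150 + sm[["mid"]] / 1.77 + w$RGR / 0.03 + w$Emax / 363
  }, numeric(1))
  sel <- switch(kind,
    complete = names(pool),
    harmful = names(sort(score, decreasing = TRUE))[1:6],
    bee_food = {
      bees <- names(pool)[vapply(pool, function(w)
        !isTRUE(w$monocot) && w$beeAttractiveness > 0, logical(1))]
      bees[order(score[bees], decreasing = TRUE)][1:6]
    })
  out <- pool[sel]
  attr(out, "kind") <- kind
  out
}

#' Create an initial weed seed bank
#'
#' Seed counts per species and 1-cm depth layer (0-30 cm), with a
#' surface-biased exponential depth distribution (most viable weed seeds sit
#' in the tilled horizon).
#'
#' @param pool weed pool from [gen_weed_pool()].
#' @param seedsPerSpecies seeds per m2 and species (recycled).
#' @param fieldArea field area in m2.
#' @param depthScale e-folding depth (cm) of the initial distribution.
#' @return matrix `species x 31` of non-negative counts, with attribute
#'   `dormantFraction` (per species, `1 - nonDormantMin`).
#' @export
new_seed_bank <- function(pool, seedsPerSpecies = 100, fieldArea = 20,
                          depthScale = 5) {
  n <- length(pool)
  tot <- round(rep_len(seedsPerSpecies, n) * fieldArea)
  w <- exp(-(0:30) / depthScale)
  w <- w / sum(w)
  bank <- t(vapply(tot, function(k) round(k * w), numeric(31)))
  rownames(bank) <- names(pool)
  colnames(bank) <- paste0("d", 0:30)
  attr(bank, "dormantFraction") <-
    vapply(pool, function(p) 1 - p$nonDormantMin, numeric(1))
  bank
}
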