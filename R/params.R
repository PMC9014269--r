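#' @useDynLib cropideo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef cor lm loess median na.omit predict prcomp
#'   quantile rbinom rlnorm rnorm rpois runif sd setNames var qnorm
#' @importFrom utils head read.csv write.csv
"_PACKAGE"

# Names of the 13 per-stage morphology / shade-response parameters.
STAGE_PARAMS <- c("SLA", "LBR", "HM", "b_HM", "WM", "b_WM", "RLH", "b_RLH",
                  "mu_SLA", "mu_LBR", "mu_HM", "mu_WM", "mu_RLH")

SCALAR_PARAMS <- c(
  "nonDormantMin", "baseWP", "g0", "g50", "gb", "darknessReduction",
  "reductionSurface", "reductionDepth",
  "shootDiameter", "shootLength", "rootLength", "r50", "rb", "gamma",
  "C0surface",
  "LA0", "se_LA", "RGR",
  "max_height", "max_width",
  "Emax", "rateWidth", "rateDepth", "rateCyl", "soilPen",
  "baseTempDev", "PeaFloweringTT", "TTflo", "TTmat",
  "tPhoto1", "tPhoto2",
  "harvestIndex", "seedMass")

#' Construct a variety parameter set
#'
#' A variety parameter set is the full per-variety parameter vector used by
#' the crop-weed simulator: germination kinetics (`g0`, `g50`, `gb`, dormancy
#' and depth/darkness reductions), pre-emergent growth (shoot/root lengths,
#' `r50`, `rb`, seedling-mortality slope `gamma`), establishment (`LA0`,
#' `se_LA`, `RGR`), per-BBCH-stage morphology (SLA, LBR, and the allometric
#' pairs HM/b_HM, WM/b_WM plus the leaf-profile pair RLH/b_RLH), per-stage
#' shade-response coefficients (`mu_*`), root-system geometry, phenology
#' (thermal-time durations), the photosynthesis temperature ramp
#' (`tPhoto1`, `tPhoto2`) and reproduction (`harvestIndex`, `seedMass`).
#'
#' @param name variety name.
#' @param seasonality one of `"spring"`, `"winter_Hr"`, `"winter_hr"`.
#' @param leafType one of `"afila"`, `"leafy"`.
#' @param scalars named list/vector covering [SCALAR_PARAMS].
#' @param stages data frame with column `stage` (0:10) and one column per
#'   entry of [STAGE_PARAMS] (11 rows).
#' @param seedAllocation optional, weeds only: g seed per g above-ground
#'   biomass in (0, 1].
#' @param beeAttractiveness optional, weeds only: non-negative weight.
#' @param monocot optional, weeds only: logical, monocot species.
#' @return an object of class `cropideo_variety`.
#' @export
variety_parameter_set <- function(name, seasonality, leafType, scalars,
                                  stages, seedAllocation = NULL,
                                  beeAttractiveness = NULL, monocot = NULL) {
  obj <- c(list(name = name, seasonality = seasonality, leafType = leafType),
           as.list(scalars)[SCALAR_PARAMS])
  obj$stages <- as.data.frame(stages)[, c("stage", STAGE_PARAMS)]
  obj$seedAllocation <- seedAllocation
  obj$beeAttractiveness <- beeAttractiveness
  obj$monocot <- monocot
  class(obj) <- "cropideo_variety"
  validate_variety(obj)
  obj
}

#' Validate a variety parameter set
#'
#' Checks the structural invariants: ordered germination thermal times
#' (`g0 < g50`), ordered photosynthesis temperatures, proportions in `[0,1]`,
#' `RLH` in (0,1), `LBR` in `[0,1]`, exactly 11 stage rows, positive seed
#' mass and phenology durations.
#'
#' @param v a `cropideo_variety`.
#' @return `v`, invisibly; errors on violation.
#' @export
validate_variety <- function(v) {
  stopifnot(inherits(v, "cropideo_variety"))
  fail <- function(msg) stop("invalid variety '", v$name, "': ", msg,
                             call. = FALSE)
  if (!is.finite(v$g0) || !is.finite(v$g50) || v$g0 >= v$g50)
    fail("g0 must be < g50")
  if (v$tPhoto1 >= v$tPhoto2) fail("tPhoto1 must be < tPhoto2")
  for (p in c("nonDormantMin", "darknessReduction", "reductionSurface",
              "soilPen", "rateCyl", "harvestIndex")) {
    if (v[[p]] < 0 || v[[p]] > 1) fail(paste(p, "must be in [0,1]"))
  }
  if (v$seedMass <= 0) fail("seedMass must be > 0")
  if (v$TTflo <= 0 || v$TTmat <= 0) fail("TTflo and TTmat must be > 0")
  if (v$gb < 1) fail("gb must be >= 1")
  st <- v$stages
  if (nrow(st) != 11L || !identical(st$stage, 0:10))
    fail("stages must have exactly 11 rows for BBCH 0..10")
  if (any(st$RLH <= 0 | st$RLH >= 1)) fail("RLH must be in (0,1)")
  if (any(st$LBR < 0 | st$LBR > 1)) fail("LBR must be in [0,1]")
  if (any(st$b_RLH < 1)) fail("b_RLH must be >= 1")
  if (!is.null(v$seedAllocation) &&
      (v$seedAllocation <= 0 || v$seedAllocation > 1))
    fail("seedAllocation must be in (0,1]")
  invisible(v)
}

#' @export
print.cropideo_variety <- function(x, ...) {
  cat("<cropideo_variety>", x$name, sprintf("(%s, %s)\n",
      x$seasonality, x$leafType))
  cat("  seed mass:", x$seedMass, "mg; harvest index:", x$harvestIndex, "\n")
  cat("  max height/width:", x$max_height, "/", x$max_width, "cm\n")
  invisible(x)
}

#' Stage array from early/mid/late anchors
#'
#' Builds an 11-entry BBCH stage array by linear interpolation through
#' anchor values placed at stages 2, 5 and 8 (clamped outside), so that
#' stages 8-10 carry the "late" value, matching the convention that named
#' early/mid/late summaries average BBCH windows `[0,4]`, `[4,8]`, `[8,10]`.
#'
#' @param early,mid,late anchor values.
#' @return numeric vector of length 11.
#' @export
stage_profile <- function(early, mid, late) {
  approx(x = c(0, 2, 5, 8, 10), y = c(early, early, mid, late, late),
         xout = 0:10)$y
}

#' Early/mid/late summaries of a stage array
#'
#' Averages an 11-entry stage array over the BBCH windows `[0,4]`, `[4,8]`
#' and `[8,10]`.
#'
#' @param values numeric vector of length 11 (stages 0..10).
#' @return named vector `c(early=, mid=, late=)`.
#' @export
stage_summary <- function(values) {
  stopifnot(length(values) == 11L)
  c(early = mean(values[1:5]), mid = mean(values[5:9]),
    late = mean(values[9:11]))
}

#' Flatten a variety to a named numeric vector
#'
#' Scalars keep their names; stage arrays become `<param>.s<stage>` entries.
#' The inverse is [unflatten_variety()].
#'
#' @param v a `cropideo_variety`.
#' @return named numeric vector.
#' @export
flatten_variety <- function(v) {
  sc <- vapply(SCALAR_PARAMS, function(p) as.numeric(v[[p]]), numeric(1))
  st <- unlist(lapply(STAGE_PARAMS, function(p)
    setNames(v$stages[[p]], paste0(p, ".s", 0:10))))
  c(sc, st)
}

#' Rebuild a variety from a flattened vector
#'
#' @param x named numeric vector as produced by [flatten_variety()].
#' @param name,seasonality,leafType identity fields (not part of the vector).
#' @param ... passed to [variety_parameter_set()] (weed-only fields).
#' @return a `cropideo_variety`.
#' @export
unflatten_variety <- function(x, name, seasonality = "spring",
                              leafType = "afila", ...) {
  stages <- data.frame(stage = 0:10)
  for (p in STAGE_PARAMS) stages[[p]] <- unname(x[paste0(p, ".s", 0:10)])
  variety_parameter_set(name, seasonality, leafType,
                        scalars = as.list(x[SCALAR_PARAMS]), stages = stages,
                        ...)
}

# Fields held constant across the reference varieties (no variety-specific
# information at parameterization time; frozen in virtual varieties too).
.pea_constants <- list(
  nonDormantMin = 1.00, baseWP = -2.30, darknessReduction = 1.00,
  reductionSurface = 0.54, shootDiameter = 2.20, rb = 1.38, gamma = 0.34,
  C0surface = 36.3, baseTempDev = 0)

# Per-variety scalar table for the seven reference pea varieties. Seed mass,
# harvest index, maximum height/width, seasonality and leaf type are the
# published per-variety measurements; the remaining entries spread each
# variety across the observed inter-variety range.
.pea_preset_table <- function() {
  tb <- list(
    #        seas        leaf     sdM   HI  mxH mxW   g0  g50   gb  redD
    Cameor  = list("spring",    "leafy", 157, 0.45,  75,  72, 16.0, 29.5, 2.30, 0.00062),
    Kayanne = list("spring",    "afila", 183, 0.52, 121,  89, 15.2, 29.0, 2.18, 0.00059),
    China   = list("winter_Hr", "leafy", 153, 0.35, 165, 100, 24.0, 31.5, 2.45, 0.00085),
    DCG0449 = list("winter_Hr", "leafy", 102, 0.30, 160, 105, 24.9, 32.0, 2.50, 0.00091),
    `886/1` = list("winter_Hr", "afila", 131, 0.40, 145, 120, 22.0, 31.0, 2.40, 0.00080),
    Enduro  = list("winter_hr", "afila", 187, 0.52, 110,  70, 18.5, 30.0, 2.25, 0.00070),
    Isard   = list("winter_hr", "afila", 153, 0.54,  97,  63, 17.0, 29.8, 2.35, 0.00065))
  more <- list(
    #        shootL rootL  r50  LA0 seLA   RGR Emax rateW rateD rateC soilP tP1 tP2 PFTT TTflo TTmat
    Cameor  = c(380, 58.0, 105, 1.20, 0.60, 0.018, 250, 5.00, 12.5, 0.15, 0.90, 0.2, 18,  880, 460, 500),
    Kayanne = c(437, 65.1, 100, 3.98, 1.96, 0.027, 301, 6.00, 15.3, 0.07, 0.82, 0.0, 15,  846, 400, 490),
    China   = c(400, 60.0, 118, 0.47, 0.39, 0.009, 213, 4.04, 10.5, 0.26, 1.00, 1.1, 27, 1250, 550, 500),
    DCG0449 = c(363, 54.8, 122, 0.80, 0.45, 0.011, 230, 4.30, 11.0, 0.24, 0.98, 0.9, 25, 1200, 520, 500),
    `886/1` = c(390, 57.0, 115, 1.00, 0.50, 0.013, 240, 4.50, 11.5, 0.20, 0.95, 0.7, 23, 1150, 500, 490),
    Enduro  = c(420, 62.0, 108, 2.50, 1.20, 0.022, 280, 5.50, 13.5, 0.10, 0.85, 0.3, 19, 1000, 450, 500),
    Isard   = c(410, 61.0, 110, 3.00, 1.50, 0.024, 290, 5.80, 14.0, 0.12, 0.88, 0.4, 17,  950, 420, 490))
  list(main = tb, more = more)
}

# Stage-parameter anchors (early, mid, late) per variety.
.pea_stage_anchors <- function() {
  list(
    SLA = list(Cameor = c(160, 140, 80), Kayanne = c(170, 150, 95),
               China = c(260, 200, 139), DCG0449 = c(250, 190, 120),
               `886/1` = c(230, 180, 110), Enduro = c(220, 170, 100),
               Isard = c(165, 145, 58.6)),
    LBR = list(Cameor = c(0.80, 0.79, 0.50), Kayanne = c(0.72, 0.75, 0.59),
               China = c(0.83, 0.82, 0.27), DCG0449 = c(0.82, 0.81, 0.30),
               `886/1` = c(0.81, 0.80, 0.35), Enduro = c(0.75, 0.77, 0.55),
               Isard = c(0.74, 0.76, 0.45)),
    HM = list(Cameor = c(10, 14, 20), Kayanne = c(25.5, 22.1, 50.4),
              China = c(20, 18, 30), DCG0449 = c(18, 17, 28),
              `886/1` = c(15, 16, 25), Enduro = c(12, 15, 22),
              Isard = c(6.5, 11.7, 15.6)),
    b_HM = list(Cameor = c(0.30, 0.28, 0.20), Kayanne = c(0.40, 0.35, 0.37),
                China = c(0.25, 0.22, 0.12), DCG0449 = c(0.28, 0.25, 0.15),
                `886/1` = c(0.32, 0.30, 0.18), Enduro = c(0.35, 0.35, 0.30),
                Isard = c(0.20, 0.20, 0.25)),
    WM = list(Cameor = c(30, 20, 15), Kayanne = c(4.3, 8, 10),
              China = c(66.2, 25, 20), DCG0449 = c(50, 22, 18),
              `886/1` = c(40, 18, 14), Enduro = c(20, 12, 11),
              Isard = c(10, 10, 9)),
    b_WM = list(Cameor = c(0.40, 0.40, 0.30), Kayanne = c(0.79, 0.60, 0.43),
                China = c(0.17, 0.21, 0.23), DCG0449 = c(0.25, 0.30, 0.28),
                `886/1` = c(0.35, 0.35, 0.32), Enduro = c(0.55, 0.50, 0.40),
                Isard = c(0.60, 0.45, 0.35)),
    RLH = list(Cameor = c(0.55, 0.50, 0.48), Kayanne = c(0.62, 0.58, 0.55),
               China = c(0.48, 0.44, 0.42), DCG0449 = c(0.50, 0.46, 0.44),
               `886/1` = c(0.52, 0.48, 0.46), Enduro = c(0.58, 0.54, 0.50),
               Isard = c(0.60, 0.56, 0.52)),
    b_RLH = list(Cameor = c(2.50, 2.30, 2.80), Kayanne = c(3.01, 2.67, 4.62),
                 China = c(2.02, 1.99, 1.94), DCG0449 = c(2.20, 2.10, 2.20),
                 `886/1` = c(2.40, 2.25, 2.60), Enduro = c(2.80, 2.50, 3.50),
                 Isard = c(2.90, 2.60, 4.00)),
    mu_SLA = list(Cameor = c(0.08, 0.30, 0.55), Kayanne = c(0.13, 0.40, 0.83),
                  China = c(0.04, 0.20, 0.45), DCG0449 = c(0.05, 0.22, 0.50),
                  `886/1` = c(0.06, 0.25, 0.52), Enduro = c(0.10, 0.35, 0.70),
                  Isard = c(0.11, 0.38, 0.75)),
    mu_LBR = list(Cameor = c(0.00, -0.10, 0.00), Kayanne = c(0.05, 0.01, 0.12),
                  China = c(-0.20, -0.30, -0.33),
                  DCG0449 = c(-0.15, -0.25, -0.28),
                  `886/1` = c(-0.10, -0.20, -0.22),
                  Enduro = c(-0.02, -0.08, 0.05),
                  Isard = c(0.02, -0.05, 0.08)),
    mu_HM = list(Cameor = c(0.20, 0.30, 0.15), Kayanne = c(0.40, 0.61, 0.30),
                 China = c(-0.10, -0.30, -0.15),
                 DCG0449 = c(0.00, -0.10, -0.05),
                 `886/1` = c(0.05, 0.00, 0.05), Enduro = c(0.15, 0.20, 0.10),
                 Isard = c(0.25, 0.35, 0.20)),
    mu_WM = list(Cameor = c(-0.05, -0.10, -0.05),
                 Kayanne = c(-0.30, -0.25, -0.20),
                 China = c(0.10, 0.20, 0.15), DCG0449 = c(0.05, 0.10, 0.08),
                 `886/1` = c(0.00, 0.05, 0.02), Enduro = c(-0.10, -0.15, -0.10),
                 Isard = c(-0.20, -0.18, -0.12)),
    mu_RLH = list(Cameor = c(0.02, 0.03, 0.02), Kayanne = c(0.08, 0.10, 0.06),
                  China = c(-0.05, -0.08, -0.04),
                  DCG0449 = c(-0.02, -0.03, -0.02),
                  `886/1` = c(0.00, 0.01, 0.00), Enduro = c(0.04, 0.05, 0.03),
                  Isard = c(0.06, 0.07, 0.05)))
}

#' Reference pea varieties
#'
#' Returns the seven parameterized reference pea varieties (Cameor, Kayanne,
#' China, DCG0449, 886/1, Enduro, Isard), spanning spring, photoperiod-
#' responsive winter (Hr) and non-responsive winter (hr) types and both
#' afila and leafy morphology. Published per-variety measurements (seed
#' mass, harvest index, maximum plant height and width in unlimited growth)
#' are set exactly; all other parameters lie inside the observed
#' inter-variety ranges. Parameters for which no variety-specific
#' information exists (e.g. `baseWP`, `reductionSurface`, `gamma`) are
#' identical across varieties.
#'
#' @return named list of 7 `cropideo_variety` objects.
#' @export
pea_reference_varieties <- function() {
  tb <- .pea_preset_table()
  anchors <- .pea_stage_anchors()
  out <- list()
  for (nm in names(tb$main)) {
    m <- tb$main[[nm]]
    e <- tb$more[[nm]]
    scalars <- c(.pea_constants, list(
      g0 = m[[7]], g50 = m[[8]], gb = m[[9]], reductionDepth = m[[10]],
      shootLength = e[1], rootLength = e[2], r50 = e[3], LA0 = e[4],
      se_LA = e[5], RGR = e[6], Emax = e[7], rateWidth = e[8],
      rateDepth = e[9], rateCyl = e[10], soilPen = e[11], tPhoto1 = e[12],
      tPhoto2 = e[13], PeaFloweringTT = e[14], TTflo = e[15], TTmat = e[16],
      seedMass = m[[3]], harvestIndex = m[[4]], max_height = m[[5]],
      max_width = m[[6]]))
    stages <- data.frame(stage = 0:10)
    for (p in STAGE_PARAMS) {
      a <- anchors[[p]][[nm]]
      stages[[p]] <- stage_profile(a[1], a[2], a[3])
    }
    out[[nm]] <- variety_parameter_set(nm, m[[1]], m[[2]], scalars, stages)
  }
  out
}

#' Write / read variety sets as JSON
#'
#' Varieties are serialized with a versioned schema field; stage arrays are
#' stored as 11-element arrays keyed by parameter.
#'
#' @param varieties named list of `cropideo_variety`.
#' @param path file path.
#' @return `read_varieties_json` returns a named list of varieties.
#' @export
write_varieties_json <- function(varieties, path) {
  enc <- lapply(varieties, function(v) {
    sc <- as.list(flatten_variety(v)[SCALAR_PARAMS])
    st <- lapply(STAGE_PARAMS, function(p) v$stages[[p]])
    names(st) <- STAGE_PARAMS
    e <- list(name = v$name, seasonality = v$seasonality,
              leafType = v$leafType, scalars = sc, stages = st)
    for (f in c("seedAllocation", "beeAttractiveness", "monocot"))
      if (!is.null(v[[f]])) e[[f]] <- v[[f]]
    e
  })
  jsonlite::write_json(list(schema = "cropideo-variety/1", varieties = enc),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_varieties_json
#' @export
read_varieties_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  stopifnot(identical(raw$schema, "cropideo-variety/1"))
  scalar_or_null <- function(x) if (length(x) == 1L) x[[1]] else NULL
  out <- lapply(raw$varieties, function(e) {
    stages <- data.frame(stage = 0:10)
    for (p in STAGE_PARAMS) stages[[p]] <- e$stages[[p]]
    variety_parameter_set(e$name, e$seasonality, e$leafType, e$scalars,
                          stages,
                          seedAllocation = scalar_or_null(e$seedAllocation),
                          beeAttractiveness =
                            scalar_or_null(e$beeAttractiveness),
                          monocot = scalar_or_null(e$monocot))
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
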