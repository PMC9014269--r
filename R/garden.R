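#' Generate a synthetic garden-plot measurement set
#'
#' Emulates isolated-plant garden-plot experiments: at each sampled BBCH
#' stage and shading-net level, individual plants are "measured" for height,
#' width, leaf area, leaf biomass, total above-ground biomass and the
#' cumulative leaf-area profile along relative height. Expectations follow
#' the generating laws of the simulator:
#' \itemize{
#' \item `height = min(HM * shadeFactor(mu_HM, s) * B^b_HM, max_height)`,
#'   width analogous with `WM`, `b_WM`, `mu_WM`, `max_width`;
#' \item `leafBiomass = LBR * shadeFactor(mu_LBR, s) * B` (capped at `B`);
#' \item `leafArea = SLA * shadeFactor(mu_SLA, s) * leafBiomass`;
#' \item the leaf profile is the cumulative model [leaf_profile_cdf()] with
#'   `RLH` shifted by `shadeFactor(mu_RLH, s)`.
#' }
#' Above-ground biomass per plant is drawn log-uniformly between 0.4 and
#' 2.5 times a stage-typical value — the large between-individual spread of
#' open-grown plants, and the leverage that identifies the allometric
#' exponents (sampling design, present even at `noiseCV = 0`); measurement
#' error is multiplicative lognormal with coefficient of variation
#' `noiseCV`.
#'
#' @param truth a `cropideo_variety` supplying the generating parameters.
#' @param stages integer BBCH stages sampled (default the five stages
#'   2, 4, 6, 8, 9 from the 2-leaf stage to end of flowering).
#' @param nPerStage plants per stage and shading level (>= 2).
#' @param shadeLevels shading intensities; must include 0, all `< 1`.
#' @param noiseCV measurement coefficient of variation (>= 0).
#' @param seed integer seed.
#' @param profilePoints number of interior leaf-profile sampling heights.
#' @return data frame (one row per plant) with a `leafProfile` list column
#'   of `(relativeHeight, cumulativeLeafAreaFraction)` data frames.
#' @export
gen_garden_plot <- function(truth, stages = c(2, 4, 6, 8, 9), nPerStage = 8,
                            shadeLevels = c(0, 0.6), noiseCV = 0.05,
                            seed = 1, profilePoints = 9) {
  stopifnot(inherits(truth, "cropideo_variety"), nPerStage >= 2)
  if (noiseCV < 0) stop("noiseCV must be >= 0")
  if (any(shadeLevels >= 1) || any(shadeLevels < 0))
    stop("shade levels must be in [0, 1)")
  if (!any(shadeLevels == 0)) stop("shadeLevels must include 0")
  sdlog <- sqrt(log(1 + noiseCV^2))
  noise <- function(n) if (noiseCV == 0) rep(1, n) else
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  # stage-typical biomass: exponential growth proxy over BBCH stage, scaled
  # so sampled plants stay below their height/width caps (isolated plants at
  # these stages do not reach the unlimited-growth asymptote)
  b_typical <- function(stage) 0.09 * exp(0.36 * stage)
  with_stream(seed, "garden", {
    rows <- list()
    profiles <- list()
    for (stage in stages) {
      st <- truth$stages[truth$stages$stage == stage, ]
      for (s in shadeLevels) {
        B <- b_typical(stage) * exp(runif(nPerStage, log(0.4), log(2.5)))
        fHM <- shade_factor(st$mu_HM, s)
        fWM <- shade_factor(st$mu_WM, s)
        fLBR <- shade_factor(st$mu_LBR, s)
        fSLA <- shade_factor(st$mu_SLA, s)
        height <- pmin(st$HM * fHM * B^st$b_HM, truth$max_height) *
          noise(nPerStage)
        width <- pmin(st$WM * fWM * B^st$b_WM, truth$max_width) *
          noise(nPerStage)
        Bobs <- B * noise(nPerStage)
        leafB <- pmin(st$LBR * fLBR, 1) * B * noise(nPerStage)
        leafB <- pmin(leafB, Bobs)
        leafA <- st$SLA * fSLA * pmin(st$LBR * fLBR, 1) * B *
          noise(nPerStage)
        rlh_eff <- min(max(st$RLH * shade_factor(st$mu_RLH, s), 1e-3),
                       1 - 1e-3)
        h <- seq(1 / (profilePoints + 1), profilePoints / (profilePoints + 1),
                 length.out = profilePoints)
        prof <- data.frame(
          relativeHeight = c(h, 1),
          cumulativeLeafAreaFraction =
            c(leaf_profile_cdf(h, rlh_eff, st$b_RLH), 1))
        for (i in seq_len(nPerStage)) {
          rows[[length(rows) + 1L]] <- data.frame(
            variety = truth$name, stageBBCH = stage, shaded = s > 0,
            shadingIntensity = s, height = height[i], width = width[i],
            leafArea = leafA[i], leafBiomass = leafB[i],
            aboveGroundBiomass = Bobs[i])
          profiles[[length(profiles) + 1L]] <- prof
        }
      }
    }
    out <- do.call(rbind, rows)
    out$leafProfile <- profiles
    out
  })
}

#' Write / read a garden-plot dataset as CSV
#'
#' One row per plant; the leaf profile is stored as a quoted JSON column.
#'
#' @param samples garden-plot data frame from [gen_garden_plot()].
#' @param path file path.
#' @export
write_garden_csv <- function(samples, path) {
  flat <- samples[, setdiff(names(samples), "leafProfile")]
  flat$leafProfile <- vapply(samples$leafProfile, function(p)
    as.character(jsonlite::toJSON(p, digits = NA)), character(1))
  write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_garden_csv
#' @export
read_garden_csv <- function(path) {
  flat <- read.csv(path, stringsAsFactors = FALSE)
  prof <- lapply(flat$leafProfile, function(s)
    as.data.frame(jsonlite::fromJSON(s)))
  flat$leafProfile <- prof
  flat
}
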