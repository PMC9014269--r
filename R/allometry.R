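#' Fit potential-morphology parameters at one stage
#'
#' Estimates the eight per-stage potential-morphology parameters from
#' unshaded plants of one variety at one BBCH stage:
#' \itemize{
#' \item `HM`, `b_HM` by least squares on the power law
#'   `height = HM * B^b_HM` (log-log OLS; the multiplicative coefficient is
#'   retransformed with the Duan smearing estimator, so noise-free data are
#'   recovered exactly and lognormal errors do not bias `HM` downward);
#'   `WM`, `b_WM` analogously on width;
#' \item `SLA` and `LBR` as ratio-of-sums estimators
#'   (`sum(leafArea)/sum(leafBiomass)` and
#'   `sum(leafBiomass)/sum(aboveGroundBiomass)`);
#' \item `RLH`, `b_RLH` from the pooled leaf profiles via
#'   [fit_leaf_profile()].
#' }
#' Exponents are reported even when near zero (clamped below at 0).
#'
#' @param samples garden-plot data frame restricted to one variety and one
#'   stage; shaded rows are dropped. Needs >= 3 unshaded plants.
#' @return data frame with columns `parameter`, `estimate`, `se`, `n`,
#'   `residVar` and attributes `stage`, `boundary`.
#' @export
fit_potential_morphology <- function(samples) {
  samples <- samples[!samples$shaded, ]
  stopifnot(length(unique(samples$stageBBCH)) == 1L)
  n <- nrow(samples)
  if (n < 3) stop("need >= 3 unshaded samples at the stage")
  if (any(samples$aboveGroundBiomass <= 0))
    stop("zero or negative above-ground biomass")
  B <- samples$aboveGroundBiomass
  power_fit <- function(y) {
    fit <- lm(log(y) ~ log(B))
    b <- unname(coef(fit)[2])
    smear <- mean(exp(stats::residuals(fit)))
    co <- exp(unname(coef(fit)[1])) * smear
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    list(coefficient = co, exponent = max(b, 0),
         se_coef = co * se[1], se_exp = unname(se[2]),
         residVar = stats::sigma(fit)^2)
  }
  hm <- power_fit(samples$height)
  wm <- power_fit(samples$width)
  sla <- sum(samples$leafArea) / sum(samples$leafBiomass)
  lbr <- sum(samples$leafBiomass) / sum(samples$aboveGroundBiomass)
  sla_se <- sd(samples$leafArea / samples$leafBiomass) / sqrt(n)
  lbr_se <- sd(samples$leafBiomass / samples$aboveGroundBiomass) / sqrt(n)
  lp <- fit_leaf_profile(samples$leafProfile, unique(samples$stageBBCH))
  out <- data.frame(
    parameter = c("SLA", "LBR", "HM", "b_HM", "WM", "b_WM", "RLH", "b_RLH"),
    estimate = c(sla, lbr, hm$coefficient, hm$exponent, wm$coefficient,
                 wm$exponent, lp$RLH, lp$b_RLH),
    se = c(sla_se, lbr_se, hm$se_coef, hm$se_exp, wm$se_coef, wm$se_exp,
           lp$se_RLH, lp$se_b_RLH),
    n = n,
    residVar = c(NA, NA, hm$residVar, NA, wm$residVar, NA, NA, NA))
  attr(out, "stage") <- unique(samples$stageBBCH)
  attr(out, "boundary") <- lp$boundary
  out
}

#' Fit the cumulative leaf-area profile
#'
#' Nonlinear least-squares fit of [leaf_profile_cdf()] to pooled
#' `(relativeHeight, cumulativeLeafAreaFraction)` points. Because the model
#' is linear on the logit scale (`logit F = b_RLH (logit h - logit RLH)`),
#' an exact OLS fit of interior points initializes the Levenberg-Marquardt
#' refinement on the original scale. A degenerate profile (all area at one
#' height) returns `b_RLH` capped at `bMax` with a boundary flag.
#'
#' @param profiles list of leaf-profile data frames (each monotone to 1).
#' @param stage BBCH stage label carried through to the result.
#' @param bMax cap for the shape parameter on degenerate profiles.
#' @return list with `RLH`, `b_RLH`, their standard errors, `stage`,
#'   `boundary`.
#' @export
fit_leaf_profile <- function(profiles, stage = NA, bMax = 50) {
  pts <- do.call(rbind, profiles)
  h <- pts$relativeHeight
  f <- pts$cumulativeLeafAreaFraction
  if (any(diff(f) < -1e-9 & diff(h) > 0) && length(profiles) == 1L)
    stop("leaf profile must be non-decreasing")
  keep <- h > 0 & h < 1 & f > 1e-9 & f < 1 - 1e-9
  if (sum(keep) < 2) {
    # everything at one height: maximally concentrated profile
    med <- stats::weighted.mean(h, c(f[1], diff(f))[seq_along(f)])
    return(list(RLH = min(max(med, 1e-3), 1 - 1e-3), b_RLH = bMax,
                se_RLH = NA_real_, se_b_RLH = NA_real_, stage = stage,
                boundary = TRUE))
  }
  u <- log(h[keep] / (1 - h[keep]))
  v <- log(f[keep] / (1 - f[keep]))
  ols <- lm(v ~ u)
  b0 <- max(unname(coef(ols)[2]), 1e-3)
  r0 <- 1 / (1 + exp(unname(coef(ols)[1]) / b0))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ leaf_profile_cdf(h, RLH, b_RLH),
      data = data.frame(h = h[keep], f = f[keep]),
      start = list(RLH = min(max(r0, 0.01), 0.99), b_RLH = min(b0, bMax)),
      lower = c(1e-3, 0.05), upper = c(1 - 1e-3, bMax),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(RLH = min(max(r0, 1e-3), 1 - 1e-3), b_RLH = min(b0, bMax),
                se_RLH = NA_real_, se_b_RLH = NA_real_, stage = stage,
                boundary = TRUE))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(NA_real_, NA_real_))
  list(RLH = unname(est["RLH"]), b_RLH = unname(est["b_RLH"]),
       se_RLH = unname(se[1]), se_b_RLH = unname(se[2]), stage = stage,
       boundary = unname(est["b_RLH"]) >= bMax - 1e-6)
}

#' Fit shade-response coefficients at one stage
#'
#' For each morphology quantity X in SLA, LBR, HM, WM, RLH, fits the
#' exponential shade law `X = X0 * exp(sign * mu_X * s)` by regressing
#' `log(X_i / X0)` on `sign * s_i` through the origin, with `X0` fixed to
#' the unshaded potential fit (reduces collinearity between `X0` and `mu`;
#' set `coEstimate = TRUE` to re-estimate `X0` jointly as a free
#' intercept). Per-plant values of HM and WM use the unshaded exponents;
#' per-plant RLH comes from each plant's own profile fit.
#'
#' @param samples garden-plot data frame for one variety and stage,
#'   shaded and unshaded; >= 2 distinct shading levels, >= 3 plants per
#'   level.
#' @param potential result of [fit_potential_morphology()] on the unshaded
#'   subset (computed internally when `NULL`).
#' @param coEstimate jointly re-estimate the unshaded level.
#' @param sign shade-law sign convention, see [shade_factor()].
#' @return data frame with columns `parameter` (`mu_*`), `estimate`, `se`,
#'   plus attributes `stage`, `levels`.
#' @export
fit_shade_response <- function(samples, potential = NULL, coEstimate = FALSE,
                               sign = getOption("cropideo.shade_sign", 1)) {
  stopifnot(length(unique(samples$stageBBCH)) == 1L)
  levels <- sort(unique(samples$shadingIntensity))
  if (length(levels) < 2)
    stop("rank deficiency: need >= 2 distinct shading levels")
  if (min(table(samples$shadingIntensity)) < 3)
    stop("need >= 3 plants per shading level")
  if (is.null(potential)) potential <- fit_potential_morphology(samples)
  pot <- setNames(potential$estimate, potential$parameter)
  B <- samples$aboveGroundBiomass
  per_plant <- list(
    SLA = samples$leafArea / samples$leafBiomass,
    LBR = samples$leafBiomass / samples$aboveGroundBiomass,
    HM = samples$height / B^pot[["b_HM"]],
    WM = samples$width / B^pot[["b_WM"]],
    RLH = vapply(samples$leafProfile, function(p)
      fit_leaf_profile(list(p))$RLH, numeric(1)))
  s <- samples$shadingIntensity
  rows <- lapply(names(per_plant), function(p) {
    y <- log(per_plant[[p]] / pot[[p]])
    x <- sign * s
    fit <- if (coEstimate) lm(y ~ x) else lm(y ~ x - 1)
    k <- if (coEstimate) 2 else 1
    data.frame(parameter = paste0("mu_", p),
               estimate = unname(coef(fit)[k]),
               se = suppressWarnings(sqrt(diag(stats::vcov(fit)))[k]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "stage") <- unique(samples$stageBBCH)
  attr(out, "levels") <- levels
  out
}

#' Interpolate stage fits to the 11 BBCH stages
#'
#' Expands each parameter's per-stage estimates to the full 11 BBCH stages.
#' The default is an interpolating local-linear profile (piecewise linear
#' through the per-stage fits): with only around five sampling stages this
#' honors every stage fit exactly, which a smoothing bandwidth would not.
#' Set `smooth = TRUE` for a loess (degree 1) smooth with bandwidth `span`,
#' appropriate for denser stage designs with replicated fits. Outside the
#' sampled stage range the profile is clamped to the nearest fitted value
#' (the garden plots cover the 2-leaf stage to end of flowering only, so
#' tail behavior is not extrapolated). Either way, exactly linear stage
#' trends are reproduced exactly and constant fits give constant profiles.
#'
#' @param fits long data frame with columns `stage`, `parameter`,
#'   `estimate` (>= 3 distinct stages). [fits_to_long()] builds it from fit
#'   objects.
#' @param span loess bandwidth (fraction of points in the local window),
#'   used when `smooth = TRUE`.
#' @param smooth use a loess smooth instead of interpolation.
#' @return data frame with columns `parameter`, `stage` (0-10), `value` and
#'   attribute `span` (`NA` for the interpolating profile).
#' @export
interpolate_bbch <- function(fits, span = 0.9, smooth = FALSE) {
  stages <- sort(unique(fits$stage))
  if (length(stages) < 3) stop("need fits at >= 3 distinct stages")
  out <- lapply(split(fits, fits$parameter), function(d) {
    d <- d[order(d$stage), ]
    xout <- pmin(pmax(0:10, min(d$stage)), max(d$stage))
    yout <- if (!smooth || nrow(d) < 4 ||
                length(unique(d$estimate)) == 1L) {
      approx(d$stage, d$estimate, xout = xout, rule = 2, ties = mean)$y
    } else {
      lo <- loess(estimate ~ stage, data = d, span = span, degree = 1,
                  surface = "direct",
                  control = stats::loess.control(statistics = "none"))
      predict(lo, data.frame(stage = xout))
    }
    data.frame(parameter = d$parameter[1], stage = 0:10, value = yout)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "span") <- if (smooth) span else NA_real_
  out
}

#' Stack per-stage fit objects into long format
#'
#' @param fits list of results of [fit_potential_morphology()] and/or
#'   [fit_shade_response()].
#' @param variety optional variety label column.
#' @return long data frame `variety, stage, parameter, estimate, se`.
#' @export
fits_to_long <- function(fits, variety = NA_character_) {
  rows <- lapply(fits, function(f)
    data.frame(variety = variety, stage = attr(f, "stage"),
               parameter = f$parameter, estimate = f$estimate, se = f$se))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate a variety's stage parameters from garden-plot data
#'
#' Convenience wrapper over the full estimation chain: per-stage potential
#' and shade fits, then BBCH interpolation, assembled into a copy of `base`
#' whose 13 stage arrays are replaced by the estimates (non-morphology
#' scalars are taken from `base`).
#'
#' @param samples garden-plot data frame for one variety.
#' @param base `cropideo_variety` supplying identity and non-morphology
#'   fields.
#' @param span loess bandwidth for [interpolate_bbch()] when
#'   `smooth = TRUE`.
#' @param smooth passed to [interpolate_bbch()].
#' @return a `cropideo_variety` with fitted stage arrays.
#' @export
fit_variety_from_garden <- function(samples, base, span = 0.9,
                                    smooth = FALSE) {
  stages <- sort(unique(samples$stageBBCH))
  fits <- list()
  for (st in stages) {
    sub <- samples[samples$stageBBCH == st, ]
    pot <- fit_potential_morphology(sub)
    fits[[length(fits) + 1L]] <- pot
    if (length(unique(sub$shadingIntensity)) >= 2)
      fits[[length(fits) + 1L]] <- fit_shade_response(sub, potential = pot)
  }
  long <- fits_to_long(fits, variety = base$name)
  prof <- interpolate_bbch(long, span = span, smooth = smooth)
  v <- base
  for (p in unique(prof$parameter))
    v$stages[[p]] <- prof$value[prof$parameter == p]
  # fitted mu_WM is present only when shade data exist for WM; any stage
  # parameter absent from the fits keeps the base value
  validate_variety(v)
  v
}
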