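# Yield and weed (dis)service indicators from paired simulation results,
# their [0,1] rescaling, and the multivariate performance profiles.

#' Crop yield loss due to weeds
#'
#' `100 * (weedFree - weedy) / weedFree` percent; negative values occur
#' when the weedy run out-yields its weed-free twin. Undefined (NA with a
#' reason attribute) when the weed-free yield is zero.
#'
#' @param weedFree,weedy yields (t/ha), vectorized.
#' @return percent loss (may be negative); NA where `weedFree` is 0.
#' @export
yield_loss <- function(weedFree, weedy) {
  out <- ifelse(weedFree > 0, 100 * (weedFree - weedy) / weedFree,
                NA_real_)
  if (anyNA(out)) attr(out, "reason") <- "weed-free yield is zero"
  out
}

#' Assemble the indicator table from paired runs
#'
#' One row per (situation, system, year, weather repetition) at the
#' `pea_year` scale (pea years only) or averaged over all crop years at
#' the `rotation` scale (rotation-scale yield then includes the other
#' crops). Raw indicators: potential yield (weed-free), weed-infested
#' yield, yield loss, field infestation (weed biomass at harvest), weed
#' species richness, bee food and herbicide applications per year.
#'
#' @param pairs list of results from [simulate_pair()]; each element may
#'   carry attributes `situation`, `systemId`, `weatherRep`.
#' @param scale `"pea_year"` or `"rotation"`.
#' @return data frame of class `cropideo_indicators`.
#' @export
compute_indicator_table <- function(pairs, scale = c("pea_year",
                                                     "rotation")) {
  scale <- match.arg(scale)
  rows <- lapply(pairs, function(p) {
    yw <- p$weedy$years
    yf <- p$weedfree$years
    if (nrow(yw) != nrow(yf) || !all(yw$year == yf$year))
      stop("pairing error: weedy and weed-free runs do not match")
    d <- data.frame(
      situation = sub("-[0-9]+$", "", p$weedy$systemId),
      systemId = p$weedy$systemId,
      weatherRep = if (is.null(p$weatherRep)) 1L else p$weatherRep,
      year = yw$year, crop = yw$crop, variety = yw$variety,
      potentialYield = yf$yield_t_ha,
      weedInfestedYield = yw$yield_t_ha,
      yieldLoss = yield_loss(yf$yield_t_ha, yw$yield_t_ha),
      fieldInfestation = yw$weedBiomass_t_ha,
      speciesRichness = yw$speciesRichness,
      beeFood = yw$beeFood,
      herbicideIntensity = yw$herbApplications)
    if (scale == "pea_year") {
      d <- d[d$crop == "pea", , drop = FALSE]
    } else {
      num <- c("potentialYield", "weedInfestedYield", "yieldLoss",
               "fieldInfestation", "speciesRichness", "beeFood",
               "herbicideIntensity")
      agg <- as.data.frame(lapply(d[num], mean, na.rm = TRUE))
      d <- cbind(d[1, c("situation", "systemId", "weatherRep")],
                 year = NA_integer_, crop = "rotation",
                 variety = d$variety[d$crop == "pea"][1], agg)
    }
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scale") <- scale
  class(out) <- c("cropideo_indicators", "data.frame")
  out
}

# Indicator direction: benefit columns (higher = better) vs harmfulness
# columns (flipped on rescaling so 1 = best = full control / zero use).
.indicator_directions <- function() {
  list(benefit = c("potentialYield", "weedInfestedYield",
                   "speciesRichness", "beeFood"),
       harm = c("yieldLoss", "fieldInfestation", "herbicideIntensity"))
}

# Rescaled twin column names.
.control_name <- function(col) {
  switch(col,
         yieldLoss = "yieldLossControl",
         fieldInfestation = "fieldInfestationControl",
         herbicideIntensity = "herbicideUseReduction",
         paste0(col, "Scaled"))
}

#' Rescale indicators to [0, 1]
#'
#' Min-max rescaling per indicator over the whole table (all situations,
#' systems, years and repetitions): the worst observed value maps to 0 and
#' the best to 1. Harmfulness indicators (yield loss, field infestation,
#' herbicide intensity) are flipped so that 1 means full control --
#' their rescaled twins are renamed `yieldLossControl`,
#' `fieldInfestationControl` and `herbicideUseReduction` (1 at zero use).
#' Constant columns map to 0.5 with a warning. Applying the function to an
#' already-rescaled table leaves the rescaled columns unchanged
#' (idempotence).
#'
#' @param table indicator table from [compute_indicator_table()].
#' @return the table with the rescaled twin columns appended/replaced.
#' @export
rescale_indicators <- function(table) {
  dirs <- .indicator_directions()
  for (col in c(dirs$benefit, dirs$harm)) {
    if (!col %in% names(table)) next
    x <- table[[col]]
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) < 1e-12) {
      warning("indicator '", col, "' is constant; rescaled to 0.5")
      y <- rep(0.5, length(x))
    } else {
      y <- (x - rng[1]) / (rng[2] - rng[1])
      if (col %in% dirs$harm) y <- 1 - y
    }
    table[[.control_name(col)]] <- y
  }
  table
}

#' Performance profiles
#'
#' The multivariate goals: `Integrated` couples weed-infested yield with
#' herbicide-use reduction; `Agroecology` adds the bee-food offer.
#'
#' @return named list of rescaled-indicator column sets.
#' @export
performance_profiles <- function() {
  list(Integrated = c("weedInfestedYieldScaled", "herbicideUseReduction"),
       Agroecology = c("weedInfestedYieldScaled", "herbicideUseReduction",
                       "beeFoodScaled"))
}

#' PCA of indicator trade-offs
#'
#' Standardized principal component analysis of the rescaled indicators,
#' optionally restricted to systems growing spring or winter pea
#' varieties, with per-variety score ellipses (mean +/- 2 SD on the first
#' two components). Constant columns are dropped with a warning.
#'
#' @param table rescaled indicator table.
#' @param varieties optional named variety list used to resolve
#'   seasonality for `varietyType` filtering.
#' @param varietyType `"all"`, `"spring"` or `"winter"`.
#' @param columns indicator columns to analyze (default: all rescaled
#'   twins present).
#' @return list with `loadings`, `scores`, `varianceShare`, `ellipses`.
#' @export
pca_tradeoffs <- function(table, varieties = NULL,
                          varietyType = c("all", "spring", "winter"),
                          columns = NULL) {
  varietyType <- match.arg(varietyType)
  if (varietyType != "all") {
    if (is.null(varieties)) stop("varieties needed to filter by type")
    season <- vapply(varieties, `[[`, "", "seasonality")
    keepVar <- names(season)[startsWith(season, if (varietyType == "spring")
      "spring" else "winter")]
    table <- table[table$variety %in% keepVar, , drop = FALSE]
  }
  if (is.null(columns)) {
    dirs <- .indicator_directions()
    columns <- vapply(c(dirs$benefit, dirs$harm), .control_name, "")
    columns <- intersect(columns, names(table))
  }
  if (nrow(table) < 3 || length(columns) < 2)
    stop("need >= 3 rows and >= 2 indicators")
  X <- as.matrix(table[, columns, drop = FALSE])
  keep <- apply(X, 2, function(x) stats::sd(x, na.rm = TRUE) > 1e-12)
  if (!all(keep)) {
    warning("dropping constant columns: ",
            paste(columns[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  X <- X[stats::complete.cases(X), , drop = FALSE]
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  shares <- p$sdev^2 / sum(p$sdev^2)
  ell <- NULL
  if ("variety" %in% names(table)) {
    sc <- as.data.frame(p$x[, 1:min(2, ncol(p$x)), drop = FALSE])
    sc$variety <- table$variety[stats::complete.cases(
      as.matrix(table[, colnames(X), drop = FALSE]))]
    ell <- do.call(rbind, lapply(split(sc, sc$variety), function(d)
      data.frame(variety = d$variety[1],
                 mPC1 = mean(d[[1]]), sdPC1 = sd(d[[1]]),
                 mPC2 = if (ncol(d) > 2) mean(d[[2]]) else NA,
                 sdPC2 = if (ncol(d) > 2) sd(d[[2]]) else NA)))
    rownames(ell) <- NULL
  }
  list(loadings = p$rotation, scores = p$x, varianceShare = shares,
       ellipses = ell)
}

#' Write / read indicator tables as tidy CSV
#'
#' @param table indicator table.
#' @param path file path.
#' @export
write_indicators_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indicators_csv
#' @export
read_indicators_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cropideo_indicators", "data.frame")
  out
}
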