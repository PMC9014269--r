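# End-to-end orchestration: varieties -> plans -> paired simulations ->
# indicators -> regression-tree analysis -> report files, reproducible
# from one master seed.

#' Pipeline configuration
#'
#' The desk-scale default (2 situations x 20 systems x 3 years x 2
#' weather repetitions, paired weedy/weed-free) runs on one CPU in
#' minutes; the full study shape (9 x 400 x 12 x 5) is configured the
#' same way and is cluster-scale.
#'
#' @param situations names of preset situations (see
#'   [situation_presets()]) or a named list of `cropideo_situation`.
#' @param nSystems cropping systems per situation.
#' @param nYears rotation years simulated per system.
#' @param nWeatherReps weather repetitions.
#' @param nVirtual virtual varieties added to the 7 reference ones.
#' @param seed master seed; every stage derives a named stream from it.
#' @param outDir output directory for the run's files.
#' @param responses rescaled indicator columns analyzed by CART.
#' @param useProfiles also analyze the multivariate performance profiles.
#' @param scales analysis scales.
#' @param nBranches best branches reported per analysis.
#' @param simConfig simulator constants ([sim_config()]).
#' @param treeConfig CART configuration ([tree_config()]).
#' @param dryRun plan and count the runs without simulating.
#' @return named list of class `cropideo_config`.
#' @export
pipeline_config <- function(situations = c("reference", "no_till"),
                            nSystems = 20, nYears = 3, nWeatherReps = 2,
                            nVirtual = 10, seed = 1,
                            outDir = file.path(tempdir(), "cropideo-run"),
                            responses = c("potentialYieldScaled",
                                          "weedInfestedYieldScaled",
                                          "yieldLossControl"),
                            useProfiles = TRUE,
                            scales = c("pea_year", "rotation"),
                            nBranches = 3,
                            simConfig = sim_config(),
                            treeConfig = tree_config(minNodeSize = 5,
                                                     maxDepth = 4),
                            dryRun = FALSE) {
  cfg <- as.list(environment())
  stopifnot(nSystems >= 1, nYears >= 1, nWeatherReps >= 1, nVirtual >= 0)
  class(cfg) <- "cropideo_config"
  cfg
}

# Key pea parameters exposed to the trees: the per-variety scalars plus
# the early/mid/late summaries of every stage parameter.
.pea_predictors <- function(v) {
  sc <- c("PeaFloweringTT", "TTflo", "TTmat", "harvestIndex", "seedMass",
          "max_height", "max_width", "tPhoto1", "tPhoto2", "g0", "g50",
          "gb", "LA0", "se_LA", "RGR", "Emax", "rateWidth", "rateDepth",
          "rateCyl", "soilPen", "shootLength", "rootLength", "r50",
          "reductionDepth")
  out <- vapply(sc, function(p) as.numeric(v[[p]]), numeric(1))
  for (p in STAGE_PARAMS) {
    sm <- stage_summary(v$stages[[p]])
    out <- c(out, setNames(sm, paste0(p, "_", names(sm))))
  }
  setNames(out, paste0("pea.", names(out)))
}

# Technique summary of one crop's operation table.
.tech_summary <- function(o) {
  c(sow = o$day[o$kind == "sowing"],
    density = o$density[o$kind == "sowing"],
    interrow = o$interrow[o$kind == "sowing"],
    depth = o$depth[o$kind == "sowing"],
    ntill = sum(o$kind == "tillage"),
    tilldepth = max(c(0, o$depth[o$kind == "tillage"]), na.rm = TRUE),
    nshred = sum(o$kind == "shredding"),
    nherb = sum(o$kind == "herbicide"),
    effmono = max(c(0, o$effMonocot), na.rm = TRUE),
    effdicot = max(c(0, o$effDicot), na.rm = TRUE),
    nmech = sum(o$kind == "mechanical_weeding"),
    residue = as.numeric(isTRUE(o$residueLeft[o$kind == "harvest"])))
}

#' Build the CART predictor table for a set of systems
#'
#' One row per system: the situation (categorical), the pea management
#' techniques (`pea_*`), the other-crop techniques averaged over the
#' rotation's non-pea crops (`oc_*`), and the pea-variety parameters
#' (`pea.` prefix: scalars and early/mid/late stage summaries).
#'
#' @param plans list of `cropideo_system` (possibly several situations).
#' @param varietyPool named list resolving each system's pea variety.
#' @return data frame keyed by `systemId` with attribute
#'   `predictorClasses` (named list of column groups).
#' @export
build_predictor_table <- function(plans, varietyPool) {
  rows <- lapply(plans, function(s) {
    pea <- .tech_summary(s$operations$pea)
    ocs <- lapply(setdiff(names(s$operations), "pea"),
                  function(cr) .tech_summary(s$operations[[cr]]))
    oc <- if (length(ocs)) colMeans(do.call(rbind, ocs)) else
      setNames(rep(0, length(pea)), names(pea))
    v <- varietyPool[[s$variety]]
    data.frame(systemId = s$systemId, situation = s$situation,
               variety = s$variety,
               as.list(setNames(pea, paste0("pea_", names(pea)))),
               as.list(setNames(oc, paste0("oc_", names(oc)))),
               as.list(.pea_predictors(v)),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cls <- list(
    situation = "situation",
    pea_parameters = grep("^pea\\.", names(out), value = TRUE),
    pea_techniques = grep("^pea_", names(out), value = TRUE),
    other_crop_techniques = grep("^oc_", names(out), value = TRUE))
  attr(out, "predictorClasses") <- cls
  out
}

# Resolve situation argument to a named list of specs.
.resolve_situations <- function(situations) {
  if (is.character(situations)) {
    pres <- situation_presets()
    missing <- setdiff(situations, names(pres))
    if (length(missing))
      stop("unknown situation(s): ", paste(missing, collapse = ", "))
    pres[situations]
  } else situations
}

#' Run the full analysis pipeline
#'
#' Executes, under one master seed: reference + virtual variety
#' construction (correlation-constrained LHS over the reference
#' envelope), per-situation LHS plans of cropping systems, paired
#' weedy/weed-free simulations over all systems and weather repetitions,
#' indicator computation and rescaling at both analysis scales, and
#' regression-tree analyses (per pea variety type, per response and
#' performance profile) with importance statistics, class-wise partial R2
#' and best-branch extraction with variety matching. All artifacts are
#' written to `config$outDir` as CSV/JSON; reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param config a `cropideo_config` from [pipeline_config()].
#' @return run manifest (list): planned/executed run counts, per-stage
#'   seeds, file inventory with MD5 checksums, timings, and (in memory)
#'   the indicator tables and analysis objects.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  seed <- config$seed
  specs <- .resolve_situations(config$situations)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  stageSeeds <- list(varieties = stream_seed(seed, "varieties"),
                     weather = stream_seed(seed, "weather"))
  # stage 1: varieties
  presets <- pea_reference_varieties()
  pool <- presets
  if (config$nVirtual > 0) {
    env <- build_envelope(presets)
    pool <- c(presets, generate_virtual_varieties(
      env, config$nVirtual, seed = stageSeeds$varieties))
  }
  write_varieties_json(pool, file.path(config$outDir, "varieties.json"))
  # stage 2: plans
  plans <- list()
  pools <- list()
  for (nm in names(specs)) {
    sd <- stream_seed(seed, paste0("plan-", nm))
    stageSeeds[[paste0("plan-", nm)]] <- sd
    plans[[nm]] <- build_plan(specs[[nm]], config$nSystems, pool,
                              seed = sd)
    pools[[nm]] <- gen_weed_pool(specs[[nm]]$weedPoolKind,
                                 seed = stream_seed(seed, "weedpool"))
    write_plan_csv(plans[[nm]],
                   file.path(config$outDir, paste0("plan-", nm, ".csv")))
  }
  # stage 3: weather repetitions
  weathers <- lapply(seq_len(config$nWeatherReps), function(r)
    gen_weather(config$nYears + 2,
                seed = stream_seed(seed, paste0("weather-", r))))
  nPlanned <- length(specs) * config$nSystems * config$nWeatherReps * 2
  if (config$dryRun) {
    man <- list(dryRun = TRUE, plannedRuns = nPlanned,
                stageSeeds = stageSeeds, config = config)
    class(man) <- "cropideo_manifest"
    return(man)
  }
  # stage 4: paired simulations
  pairsAll <- list()
  for (nm in names(specs)) {
    bank <- new_seed_bank(pools[[nm]],
                          fieldArea = config$simConfig$fieldArea)
    for (s in plans[[nm]]) {
      for (r in seq_len(config$nWeatherReps)) {
        pr <- simulate_pair(
          s, pool, pools[[nm]], weathers[[r]], bank,
          seed = stream_seed(seed, paste("sim", s$systemId, r)),
          nYears = config$nYears, config = config$simConfig)
        pr$weatherRep <- r
        pairsAll[[length(pairsAll) + 1L]] <- pr
      }
    }
  }
  # stage 5: indicators
  tables <- list()
  for (sc in config$scales) {
    tb <- compute_indicator_table(pairsAll, scale = sc)
    tb <- rescale_indicators(tb)
    tables[[sc]] <- tb
    write_indicators_csv(tb, file.path(config$outDir,
                                       paste0("indicators-", sc, ".csv")))
  }
  # stage 6: analysis
  X <- build_predictor_table(do.call(c, unname(plans)), pool)
  classes <- attr(X, "predictorClasses")
  season <- vapply(pool, `[[`, "", "seasonality")
  analyses <- list()
  respSets <- c(as.list(setNames(config$responses, config$responses)),
                if (config$useProfiles) performance_profiles())
  for (sc in config$scales) {
    tb <- tables[[sc]]
    for (vt in c("spring", "winter")) {
      keepVar <- names(season)[startsWith(season, vt)]
      rows <- tb[tb$variety %in% keepVar, , drop = FALSE]
      if (nrow(rows) < 2 * config$treeConfig$minNodeSize) next
      Xr <- X[match(rows$systemId, X$systemId), , drop = FALSE]
      Xp <- Xr[, setdiff(names(Xr), c("systemId", "variety")),
               drop = FALSE]
      for (rn in names(respSets)) {
        cols <- respSets[[rn]]
        if (!all(cols %in% names(rows))) next
        Y <- as.matrix(rows[, cols, drop = FALSE])
        if (any(apply(Y, 2, sd) < 1e-12)) next
        tr <- grow_tree(Xp, Y, config$treeConfig)
        pr <- prune_cv(tr, folds = min(10, nrow(Y)),
                       seed = stream_seed(seed, paste("cv", sc, vt, rn)))
        imp <- tree_importance(pr, classes)
        brs <- select_best_branches(
          pr, config$nBranches,
          if (length(cols) > 1) "multivariate" else "univariate")
        matched <- lapply(brs, function(b) match_varieties(b, pool))
        analyses[[paste(sc, vt, rn, sep = "|")]] <-
          list(scale = sc, varietyType = vt, response = rn, tree = pr,
               importance = imp, branches = brs, matched = matched)
      }
    }
  }
  files <- if (length(analyses)) write_report(analyses, config$outDir)
    else {
      warning("too few rows per variety type for tree analysis; ",
              "no report written")
      character(0)
    }
  files <- c(file.path(config$outDir,
                       c("varieties.json",
                         paste0("plan-", names(specs), ".csv"),
                         paste0("indicators-", config$scales, ".csv"))),
             files)
  man <- list(dryRun = FALSE, plannedRuns = nPlanned,
              executedRuns = 2 * length(pairsAll),
              stageSeeds = stageSeeds,
              files = data.frame(file = basename(files),
                                 md5 = unname(tools::md5sum(files))),
              elapsedSec = as.numeric(Sys.time() - t0, units = "secs"),
              tables = tables, analyses = analyses, pool = pool,
              config = config)
  class(man) <- "cropideo_manifest"
  man
}

#' @export
print.cropideo_manifest <- function(x, ...) {
  cat("<cropideo_manifest>", if (x$dryRun) "dry run;" else "",
      x$plannedRuns, "runs planned",
      if (!x$dryRun) paste0("(", x$executedRuns, " executed in ",
                            round(x$elapsedSec), " s)"), "\n")
  invisible(x)
}

#' Write the report files of a set of tree analyses
#'
#' Emits the class-wise partial-R2 grid (rows: pea parameters, pea
#' techniques, other-crop techniques, situation; columns: responses and
#' profiles; one block per variety type and scale), the best-branch
#' listings (rules with thresholds and ranks, leaf shares and means,
#' matching varieties) and the per-predictor importance tables.
#'
#' @param analyses named list of analysis results (see [run_pipeline()]).
#' @param outDir output directory.
#' @return character vector of written file paths.
#' @export
write_report <- function(analyses, outDir) {
  if (!length(analyses)) stop("no completed analyses to report")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  grid <- do.call(rbind, lapply(analyses, function(a) {
    cls <- a$importance$classes
    data.frame(scale = a$scale, varietyType = a$varietyType,
               response = a$response, class = cls$class,
               partialR2 = round(cls$partialR2, 4),
               totalR2 = round(a$importance$R2, 4))
  }))
  rownames(grid) <- NULL
  # Wide grid: one row per class within (scale, varietyType)
  wide <- stats::reshape(
    grid, idvar = c("scale", "varietyType", "class"),
    timevar = "response", direction = "wide", v.names = "partialR2",
    drop = "totalR2")
  names(wide) <- sub("^partialR2\\.", "", names(wide))
  f1 <- file.path(outDir, "class-partial-r2.csv")
  write.csv(wide, f1, row.names = FALSE)
  branches <- do.call(rbind, lapply(names(analyses), function(nm) {
    a <- analyses[[nm]]
    do.call(rbind, lapply(seq_along(a$branches), function(bi) {
      b <- a$branches[[bi]]
      data.frame(scale = a$scale, varietyType = a$varietyType,
                 response = a$response, branch = bi,
                 share = round(b$share, 4), score = round(b$score, 4),
                 rules = paste(format_branch(b), collapse = "; "),
                 varieties = paste(a$matched[[bi]], collapse = " "))
    }))
  }))
  f2 <- file.path(outDir, "best-branches.csv")
  write.csv(branches, f2, row.names = FALSE)
  imp <- do.call(rbind, lapply(analyses, function(a)
    cbind(scale = a$scale, varietyType = a$varietyType,
          response = a$response, a$importance$table)))
  rownames(imp) <- NULL
  imp$VIP <- round(imp$VIP, 6)
  imp$relVIP <- round(imp$relVIP, 6)
  imp$partialR2 <- round(imp$partialR2, 6)
  imp$probIncrease <- round(imp$probIncrease, 6)
  f3 <- file.path(outDir, "importance.csv")
  write.csv(imp, f3, row.names = FALSE)
  c(f1, f2, f3)
}
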