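# Build LHS-stratified cropping systems within a situation.
#
# Continuous technique variables are stratified across the systems of a
# plan (one Latin-hypercube row per system); categorical choices (variety,
# rotation order, residue handling) are sampled uniformly. "Agronomic
# logic" is codified in the rule table of `.crop_rules()`: per-crop sowing
# windows, tillage strictly before sowing, herbicide/mechanical weeding
# timed relative to sowing, harvest after full maturation (checked against
# each variety's thermal-time requirement under the climatological year).

# Continuous technique variables sampled per crop (quantile columns).
.tech_vars <- c("sow_q", "dens_q", "inter_q", "depth_q", "ntill_q",
                "tilldepth_q", "firsttill_q", "lasttill_q", "nshred_q",
                "nherb_q", "effmono_q", "effdicot_q", "herbdelay_q",
                "nmech_q", "mechdelay_q", "residue_q")

.op_row <- function(kind, day, crop, depth = NA, density = NA,
                    interrow = NA, effMonocot = NA, effDicot = NA,
                    residueLeft = NA, fertilizer = NA_character_) {
  data.frame(kind = kind, day = as.numeric(day), crop = crop, depth = depth,
             density = density, interrow = interrow,
             effMonocot = effMonocot, effDicot = effDicot,
             residueLeft = residueLeft, fertilizer = fertilizer,
             stringsAsFactors = FALSE)
}

#' Sample one crop-year's management operations
#'
#' Maps a row of stratified quantiles onto dated, parameterized operations
#' for one crop under a situation's constraints: summer-fallow tillage
#' (false seed bed) and residue shredding between the previous harvest and
#' sowing, sowing inside the crop's window (clamped earlier if the drawn
#' date would not let the variety reach full maturity under the
#' climatological year), post-sowing herbicides and mechanical weeding
#' where permitted, fertilization, and harvest at estimated maturity.
#' All dates are crop-year offsets (day 0 = 1 August).
#'
#' @param crop crop name.
#' @param spec a `cropideo_situation`.
#' @param lhsRow named vector of quantiles in `[0,1]` for [.tech_vars].
#' @param variety `cropideo_variety` grown (pea variety or crop preset).
#' @param climate climate list for the maturation check.
#' @param maxRetries attempts to find a maturable sowing date.
#' @param maturityMargin extra thermal time (degC d) required beyond the
#'   variety's maturation requirement, buffering interannual temperature
#'   variability so scheduled harvests fall after full maturity.
#' @return data frame of operations (columns `kind`, `day`, `crop`,
#'   option columns).
#' @export
sample_crop_techniques <- function(crop, spec, lhsRow, variety,
                                   climate = default_climate(),
                                   maxRetries = 50,
                                   maturityMargin = 250) {
  rules <- .crop_rules()
  r <- rules[rules$crop == crop, ]
  if (nrow(r) != 1L) stop("unknown crop: ", crop)
  q <- function(nm) unname(lhsRow[[nm]])
  ctt <- .climatological_tt(climate)
  need <- .tt_requirement(variety) + maturityMargin
  H <- 446L  # maturity must fall before the crop-year horizon (offset 445)
  sow_feasible <- function(day) {
    i <- round(day) + 1L
    if (i + 30L > H) return(FALSE)
    any(ctt[seq(i + 30L, H)] - ctt[i] >= need)
  }
  sow <- r$sowMin + q("sow_q") * (r$sowMax - r$sowMin)
  tries <- 0
  while (!sow_feasible(sow)) {
    tries <- tries + 1
    if (tries > maxRetries)
      stop("constraint error: no sowing date in the ", crop,
           " window lets variety '", variety$name, "' reach maturity")
    sow <- max(r$sowMin, sow - (r$sowMax - r$sowMin) / maxRetries * 2)
    if (sow <= r$sowMin && !sow_feasible(sow))
      stop("constraint error: no sowing date in the ", crop,
           " window lets variety '", variety$name, "' reach maturity")
  }
  sow <- round(sow)
  i <- sow + 1L
  matIdx <- which(ctt[seq_len(H)] - ctt[i] >= need &
                    seq_len(H) > i)[1]
  harvest <- matIdx - 1L + 5L
  ops <- list()
  # summer fallow: false seed bed tillage and shredding before sowing
  if (spec$tillageAllowed) {
    ntill <- floor(q("ntill_q") * 6.999)
    firstTill <- 1 + round(q("firsttill_q") * min(59, sow - 2))
    lastGap <- round(q("lasttill_q") * 127)
    lastTill <- max(firstTill, sow - 1 - lastGap)
    depth <- q("tilldepth_q") * 29
    if (ntill > 0) {
      days <- unique(round(seq(firstTill, lastTill, length.out = ntill)))
      for (d in days)
        ops[[length(ops) + 1L]] <- .op_row("tillage", d, crop, depth = depth)
    }
    # sowing-bed preparation pass (shallow) always precedes drilling
    ops[[length(ops) + 1L]] <- .op_row("tillage", sow - 1, crop,
                                       depth = min(depth, 5))
  }
  nshred <- floor(q("nshred_q") * 2.999)
  if (nshred > 0 && sow > 20) {
    for (d in round(seq(5, max(6, sow - 10), length.out = nshred)))
      ops[[length(ops) + 1L]] <- .op_row("shredding", d, crop)
  }
  dens <- r$densMin + q("dens_q") * (r$densMax - r$densMin)
  inter <- r$interMin + q("inter_q") * (r$interMax - r$interMin)
  # shallow drilling only: the ln(mm) depth-mortality law makes emergence
  # from below ~1.5 cm negligible
  sdepth <- 0.3 + q("depth_q") * 0.9
  ops[[length(ops) + 1L]] <- .op_row("sowing", sow, crop, depth = sdepth,
                                     density = dens, interrow = inter)
  if (spec$herbicidesAllowed) {
    nherb <- floor(q("nherb_q") * 2.999)
    if (nherb > 0) {
      d0 <- 1 + round(q("herbdelay_q") * 119)
      for (k in seq_len(nherb))
        ops[[length(ops) + 1L]] <- .op_row(
          "herbicide", min(sow + d0 + (k - 1) * 14, harvest - 5), crop,
          effMonocot = q("effmono_q"), effDicot = q("effdicot_q"))
    }
  }
  if (spec$mechanicalWeedingAllowed) {
    nmech <- floor(q("nmech_q") * 5.999)
    if (nmech > 0) {
      d0 <- 10 + round(q("mechdelay_q") * 50)
      for (k in seq_len(nmech))
        ops[[length(ops) + 1L]] <- .op_row(
          "mechanical_weeding", min(sow + d0 + (k - 1) * 14, harvest - 5),
          crop)
    }
  }
  ops[[length(ops) + 1L]] <- .op_row("fertilization", sow + 30, crop,
                                     fertilizer = spec$fertilizerType)
  ops[[length(ops) + 1L]] <- .op_row("harvest", harvest, crop,
                                     residueLeft = q("residue_q") < 0.5)
  out <- do.call(rbind, ops)
  out <- out[order(out$day, match(out$kind, c(
    "tillage", "shredding", "sowing", "fertilization", "herbicide",
    "mechanical_weeding", "rolling", "harvest"))), ]
  rownames(out) <- NULL
  out
}

#' Build an LHS plan of cropping systems for one situation
#'
#' Each system gets a random rotation (a permutation of the situation's
#' allowed crops, repeated cyclically at simulation time), a pea variety
#' drawn uniformly from the pool, and per-crop management sampled by
#' [sample_crop_techniques()] from one row of a Latin hypercube over all
#' continuous technique variables (so each technique variable is
#' stratified across the plan's systems).
#'
#' @param spec a `cropideo_situation`.
#' @param nSystems number of systems.
#' @param varietyPool named list of pea `cropideo_variety` candidates.
#' @param seed integer seed.
#' @param climate climate list for maturation checks.
#' @return list of `cropideo_system` objects.
#' @export
build_plan <- function(spec, nSystems, varietyPool, seed = 1,
                       climate = default_climate()) {
  stopifnot(inherits(spec, "cropideo_situation"), length(varietyPool) >= 1)
  crops <- spec$crops
  presets <- crop_presets()
  nv <- length(.tech_vars)
  cols <- as.vector(outer(.tech_vars, crops, function(v, cr)
    paste(cr, v, sep = ".")))
  U <- with_stream(seed, paste0("plan-", spec$name),
                   lhs::randomLHS(nSystems, length(cols)))
  colnames(U) <- cols
  systems <- vector("list", nSystems)
  for (i in seq_len(nSystems)) {
    rot <- with_stream(seed, paste0("rot-", spec$name, "-", i),
                       sample(crops))
    vIdx <- with_stream(seed, paste0("var-", spec$name, "-", i),
                        sample.int(length(varietyPool), 1))
    variety <- varietyPool[[vIdx]]
    ops <- list()
    for (cr in crops) {
      lhsRow <- setNames(U[i, paste(cr, .tech_vars, sep = ".")], .tech_vars)
      v <- if (cr == "pea") variety else presets[[cr]]
      o <- sample_crop_techniques(cr, spec, lhsRow, v, climate = climate)
      ops[[cr]] <- o
    }
    sys <- list(situation = spec$name, systemId =
                  sprintf("%s-%03d", spec$name, i),
                rotation = rot, variety = variety$name,
                operations = ops, lhsRow = U[i, ], spec = spec)
    class(sys) <- "cropideo_system"
    systems[[i]] <- sys
  }
  systems
}

#' @export
print.cropideo_system <- function(x, ...) {
  cat("<cropideo_system>", x$systemId, " rotation:",
      paste(x$rotation, collapse = " > "), " pea variety:", x$variety, "\n")
  invisible(x)
}

#' Validate a cropping system against its situation
#'
#' Pure post-hoc checker: rotation within allowed crops with pea present
#' and no crop repeated, forbidden operation kinds absent, no tillage
#' between sowing and harvest within each crop-year, sowing before
#' harvest, and option values inside their envelopes.
#'
#' @param system a `cropideo_system`.
#' @return `TRUE` invisibly; errors describing the first violation.
#' @export
validate_cropping_system <- function(system) {
  spec <- system$spec
  if (!all(system$rotation %in% spec$crops)) stop("rotation outside spec")
  if (anyDuplicated(system$rotation)) stop("crop repeated in rotation")
  if (!"pea" %in% system$rotation) stop("pea absent from rotation")
  rules <- .crop_rules()
  for (cr in names(system$operations)) {
    o <- system$operations[[cr]]
    r <- rules[rules$crop == cr, ]
    if (!spec$tillageAllowed && any(o$kind == "tillage"))
      stop("tillage operation in no-till system")
    if (!spec$herbicidesAllowed && any(o$kind == "herbicide"))
      stop("herbicide operation where not allowed")
    if (!spec$mechanicalWeedingAllowed &&
        any(o$kind == "mechanical_weeding"))
      stop("mechanical weeding where not allowed")
    sow <- o$day[o$kind == "sowing"]
    harv <- o$day[o$kind == "harvest"]
    if (length(sow) != 1L || length(harv) != 1L) stop("need one sowing and one harvest")
    if (sow >= harv) stop("sowing must precede harvest")
    if (any(o$kind == "tillage" & o$day >= sow))
      stop("tillage after crop sowing")
    if (sow < r$sowMin || sow > r$sowMax) stop("sowing outside crop window")
    dens <- o$density[o$kind == "sowing"]
    if (dens < r$densMin - 1e-9 || dens > r$densMax + 1e-9)
      stop("sowing density outside envelope")
    if (any(o$depth[o$kind == "tillage"] > 29 + 1e-9))
      stop("tillage depth above envelope")
  }
  invisible(TRUE)
}

#' Audit the decorrelation of a simulation plan
#'
#' Encodes each system as numeric columns in three factor groups --
#' management techniques (sowing date/density/interrow, tillage counts and
#' depths, herbicide and weeding intensity), rotation structure (length,
#' pea position, crop presence) and pea-variety parameters (key scalars) --
#' and reports the median absolute Pearson correlation within and between
#' groups. Constant columns are dropped; an all-identical plan reports
#' `NA` ("not applicable").
#'
#' @param plan list of `cropideo_system` (>= 10).
#' @param varietyPool named variety list used to resolve each system's pea
#'   parameters (defaults to the reference varieties).
#' @return list with the encoded `columns` data frame and a `report` data
#'   frame `group1, group2, medianAbsR, n`.
#' @export
audit_plan_correlations <- function(plan, varietyPool = NULL) {
  stopifnot(length(plan) >= 10)
  if (is.null(varietyPool)) varietyPool <- pea_reference_varieties()
  enc <- lapply(plan, function(s) {
    pea <- s$operations$pea
    sow <- pea$day[pea$kind == "sowing"]
    v <- varietyPool[[s$variety]]
    tech <- c(pea_sow = sow,
              pea_density = pea$density[pea$kind == "sowing"],
              pea_interrow = pea$interrow[pea$kind == "sowing"],
              pea_ntill = sum(pea$kind == "tillage"),
              pea_tilldepth = suppressWarnings(
                max(c(0, pea$depth[pea$kind == "tillage"]), na.rm = TRUE)),
              pea_nherb = sum(pea$kind == "herbicide"),
              pea_effmono = suppressWarnings(
                max(c(0, pea$effMonocot), na.rm = TRUE)),
              pea_nmech = sum(pea$kind == "mechanical_weeding"),
              pea_residue = as.numeric(
                pea$residueLeft[pea$kind == "harvest"]))
    rot <- c(rot_length = length(s$rotation),
             pea_position = match("pea", s$rotation),
             setNames(as.numeric(c("winter_wheat", "WOSR", "barley",
                                   "sunflower", "maize") %in% s$rotation),
                      paste0("has_", c("WW", "WOSR", "B", "S", "M"))))
    par <- if (!is.null(v))
      c(v_floweringTT = v$PeaFloweringTT, v_harvestIndex = v$harvestIndex,
        v_maxHeight = v$max_height, v_seedMass = v$seedMass,
        v_tPhoto2 = v$tPhoto2, v_g0 = v$g0,
        v_muHMmid = stage_summary(v$stages$mu_HM)[["mid"]])
    else c(v_missing = NA_real_)
    c(tech, rot, par)
  })
  X <- do.call(rbind, enc)
  groups <- c(rep("technique", 9), rep("rotation", 7),
              rep("variety", ncol(X) - 16))
  keep <- apply(X, 2, function(x) length(unique(x)) > 1 && !anyNA(x))
  pairs <- expand.grid(g1 = unique(groups), g2 = unique(groups),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$g1 <= pairs$g2, ]
  rep <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    i <- which(groups == pairs$g1[k] & keep)
    j <- which(groups == pairs$g2[k] & keep)
    if (length(i) == 0 || length(j) == 0)
      return(data.frame(group1 = pairs$g1[k], group2 = pairs$g2[k],
                        medianAbsR = NA_real_, n = 0L))
    C <- cor(X[, i, drop = FALSE], X[, j, drop = FALSE])
    if (identical(pairs$g1[k], pairs$g2[k])) {
      vals <- abs(C[upper.tri(C)])
    } else vals <- abs(as.vector(C))
    data.frame(group1 = pairs$g1[k], group2 = pairs$g2[k],
               medianAbsR = if (length(vals)) median(vals) else NA_real_,
               n = length(vals))
  }))
  list(columns = as.data.frame(X), report = rep)
}

#' Write a plan to CSV (one row per operation) with a JSON manifest
#'
#' @param plan list of `cropideo_system`.
#' @param csvPath,manifestPath output paths.
#' @export
write_plan_csv <- function(plan, csvPath, manifestPath = NULL) {
  rows <- lapply(plan, function(s) {
    do.call(rbind, lapply(names(s$operations), function(cr) {
      o <- s$operations[[cr]]
      cbind(systemId = s$systemId, situation = s$situation,
            rotation = paste(s$rotation, collapse = ">"),
            variety = s$variety, o)
    }))
  })
  write.csv(do.call(rbind, rows), csvPath, row.names = FALSE)
  if (!is.null(manifestPath)) {
    jsonlite::write_json(
      list(schema = "cropideo-plan/1",
           situation = plan[[1]]$situation, nSystems = length(plan),
           varieties = vapply(plan, `[[`, "", "variety")),
      manifestPath, auto_unbox = TRUE)
  }
  invisible(csvPath)
}
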