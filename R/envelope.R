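# Inter-variety parameter envelope and correlation-constrained LHS.
#
# The envelope works on a transformed flat coordinate system in which the
# ordered pairs (g0, g50) and (tPhoto1, tPhoto2) are represented as
# (lower, positive gap), so that joint sampling can never violate the order
# constraints; the public variety objects always carry the natural
# parameters.

.to_envelope_coords <- function(x) {
  x["g50"] <- x["g50"] - x["g0"]
  names(x)[names(x) == "g50"] <- "g50gap"
  x["tPhoto2"] <- x["tPhoto2"] - x["tPhoto1"]
  names(x)[names(x) == "tPhoto2"] <- "tPhoto2gap"
  x
}

.from_envelope_coords <- function(x) {
  x["g50gap"] <- x["g50gap"] + x["g0"]
  names(x)[names(x) == "g50gap"] <- "g50"
  x["tPhoto2gap"] <- x["tPhoto2gap"] + x["tPhoto1"]
  names(x)[names(x) == "tPhoto2gap"] <- "tPhoto2"
  x
}

# Biological hard caps per (transformed) parameter name.
.hard_caps <- function(names) {
  lo <- rep(-Inf, length(names))
  hi <- rep(Inf, length(names))
  prop <- names %in% c("nonDormantMin", "darknessReduction",
                       "reductionSurface", "soilPen", "rateCyl",
                       "harvestIndex") | grepl("^LBR\\.", names)
  lo[prop] <- 0; hi[prop] <- 1
  rlh <- grepl("^RLH\\.", names)
  lo[rlh] <- 0.01; hi[rlh] <- 0.99
  shape1 <- names == "gb" | grepl("^b_RLH\\.", names)
  lo[shape1] <- 1
  pos <- names %in% c("g0", "g50gap", "tPhoto2gap", "reductionDepth",
                      "shootDiameter", "shootLength", "rootLength", "r50",
                      "rb", "C0surface", "LA0", "se_LA", "RGR",
                      "max_height", "max_width", "Emax", "rateWidth",
                      "rateDepth", "PeaFloweringTT", "TTflo", "TTmat",
                      "seedMass") |
    grepl("^(SLA|HM|WM)\\.", names)
  lo[pos] <- pmax(lo[pos], 1e-6)
  zero <- names %in% c("gamma") | grepl("^(b_HM|b_WM)\\.", names)
  lo[zero] <- pmax(lo[zero], 0)
  hi[names == "baseWP"] <- 0
  data.frame(name = names, low = lo, high = hi, stringsAsFactors = FALSE)
}

#' Build the inter-variety parameter envelope
#'
#' Computes, over the flattened parameter vectors of the supplied
#' varieties, each parameter's observed range, the extended sampling range
#' (outward extension by 10% of the bound's magnitude, capped into
#' biological hard limits such as `[0, 1]` for proportions), and the
#' Pearson correlation matrix across varieties. Parameters constant across
#' varieties get a zero-width range and zero off-diagonal correlation. The
#' correlation matrix is repaired to the nearest positive semi-definite
#' matrix (eigenvalue clipping at 1e-8, rescaled to unit diagonal) when
#' sample noise makes it indefinite.
#'
#' @param varieties list of >= 3 `cropideo_variety` objects.
#' @param caps optional data frame overriding the default hard caps
#'   (`name`, `low`, `high`).
#' @return object of class `cropideo_envelope`.
#' @export
build_envelope <- function(varieties, caps = NULL) {
  if (length(varieties) < 3)
    stop("need >= 3 varieties to build an envelope")
  M <- t(vapply(varieties, function(v) .to_envelope_coords(flatten_variety(v)),
                numeric(length(flatten_variety(varieties[[1]])))))
  nm <- colnames(M)
  capdf <- .hard_caps(nm)
  if (!is.null(caps)) {
    i <- match(caps$name, capdf$name)
    capdf$low[i] <- caps$low
    capdf$high[i] <- caps$high
  }
  mn <- apply(M, 2, min)
  mx <- apply(M, 2, max)
  extLo <- setNames(pmax(capdf$low, mn - 0.1 * abs(mn)), nm)
  extHi <- setNames(pmin(capdf$high, mx + 0.1 * abs(mx)), nm)
  constant <- (mx - mn) < 1e-12
  extLo[constant] <- mn[constant]
  extHi[constant] <- mx[constant]
  C <- diag(length(nm))
  vary <- which(!constant)
  if (length(vary) >= 2)
    C[vary, vary] <- cor(M[, vary, drop = FALSE])
  rep <- repair_psd(C)
  env <- list(names = nm, min = mn, max = mx, extendedMin = extLo,
              extendedMax = extHi, hardCapLow = capdf$low,
              hardCapHigh = capdf$high, constant = constant,
              corr = rep$matrix, psdRepaired = rep$repaired,
              nVarieties = length(varieties))
  class(env) <- "cropideo_envelope"
  env
}

#' @export
print.cropideo_envelope <- function(x, ...) {
  cat("<cropideo_envelope>", length(x$names), "parameters from",
      x$nVarieties, "varieties;", sum(!x$constant), "vary\n")
  invisible(x)
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Eigenvalue clipping at `eps`, then rescaling to unit diagonal.
#'
#' @param C symmetric matrix with unit diagonal.
#' @param eps smallest admitted eigenvalue.
#' @return list `matrix` (repaired), `repaired` (logical).
#' @export
repair_psd <- function(C, eps = 1e-8) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(e$values) >= eps) return(list(matrix = C, repaired = FALSE))
  v <- pmax(e$values, eps)
  M <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  list(matrix = M, repaired = TRUE)
}

#' Correlation-constrained Latin hypercube sample
#'
#' Draws `n` rows by Latin hypercube sampling (each column occupies the `n`
#' equiprobable strata of `[0, 1]` exactly once) and induces a target rank
#' correlation structure with the Iman-Conover procedure: a matrix of van
#' der Waerden normal scores is given the target Pearson structure through
#' its Cholesky factor, and each LHS column is reordered to match the ranks
#' of the corresponding score column. Reordering permutes within columns,
#' so the LHS marginal property is preserved exactly, and rank correlations
#' are invariant to strictly monotone transformations of the margins.
#'
#' @param n number of draws (>= 2).
#' @param target target correlation matrix (treated as the target Spearman
#'   rank correlation), `p x p`.
#' @param seed integer seed.
#' @return `n x p` matrix in `[0, 1]` with stratified margins.
#' @export
lhs_correlated <- function(n, target, seed = 1) {
  stopifnot(n >= 2, is.matrix(target), nrow(target) == ncol(target))
  p <- nrow(target)
  rep <- repair_psd(target)
  ch <- tryCatch(chol(rep$matrix + diag(1e-9, p)), error = function(e) NULL)
  if (is.null(ch)) {
    cond <- structure(class = c("cropideo_corr_error", "error", "condition"),
                      list(message = "correlation matrix infeasible after PSD repair",
                           call = sys.call(-1), matrix = rep$matrix))
    stop(cond)
  }
  with_stream(seed, "lhs", {
    U <- lhs::randomLHS(n, p)
    a <- qnorm((1:n) / (n + 1))
    S <- vapply(seq_len(p), function(j) sample(a), numeric(n))
    # de-correlate the raw scores before imposing the target; only possible
    # when the empirical score correlation is invertible (n sufficiently
    # larger than p), otherwise impose the target on the raw scores
    Sstar <- if (n > p + 1) {
      E <- cor(S)
      chE <- tryCatch(chol(E), error = function(e) NULL)
      if (is.null(chE)) S %*% ch else S %*% solve(chE) %*% ch
    } else S %*% ch
    out <- U
    for (j in seq_len(p)) out[, j] <- sort(U[, j])[rank(Sstar[, j],
                                                        ties.method = "first")]
    out
  })
}

#' Generate virtual varieties from an envelope
#'
#' Draws `n` virtual parameter vectors by correlation-constrained LHS over
#' the envelope's extended ranges ([lhs_correlated()]), freezes parameters
#' that do not vary among the actual varieties at their common value, maps
#' the ordered pairs (g0, g50) and (tPhoto1, tPhoto2) back from their
#' (lower, gap) sampling coordinates, and re-validates every variety.
#' Virtual varieties are labelled spring or winter by their sampled
#' flowering thermal time (threshold `winterTT`): long-cycle parameter
#' vectors behave as winter types in the rotation.
#'
#' @param envelope a `cropideo_envelope`.
#' @param n number of virtual varieties (>= 2).
#' @param seed integer seed.
#' @param prefix name prefix, varieties are named `<prefix>1 .. <prefix>n`.
#' @param winterTT flowering thermal-time threshold (degC d) separating
#'   spring from winter labels.
#' @return named list of `cropideo_variety`.
#' @export
generate_virtual_varieties <- function(envelope, n, seed = 1,
                                       prefix = "Virtual", winterTT = 1000) {
  stopifnot(inherits(envelope, "cropideo_envelope"), n >= 2)
  vary <- which(!envelope$constant)
  U <- lhs_correlated(n, envelope$corr[vary, vary, drop = FALSE], seed)
  lo <- envelope$extendedMin[vary]
  hi <- envelope$extendedMax[vary]
  out <- list()
  for (i in seq_len(n)) {
    x <- envelope$min  # constants at their common value
    x[vary] <- lo + U[i, ] * (hi - lo)
    names(x) <- envelope$names
    x <- .from_envelope_coords(x)
    season <- if (x[["PeaFloweringTT"]] < winterTT) "spring" else "winter_hr"
    nm <- paste0(prefix, i)
    out[[nm]] <- unflatten_variety(x, nm, seasonality = season,
                                   leafType = "afila")
  }
  out
}

#' Envelope JSON round trip
#'
#' @param envelope a `cropideo_envelope`.
#' @param path file path.
#' @export
write_envelope_json <- function(envelope, path) {
  jsonlite::write_json(
    list(schema = "cropideo-envelope/1",
         names = envelope$names, min = envelope$min, max = envelope$max,
         extendedMin = envelope$extendedMin,
         extendedMax = envelope$extendedMax,
         hardCapLow = envelope$hardCapLow,
         hardCapHigh = envelope$hardCapHigh,
         constant = envelope$constant, corr = envelope$corr,
         psdRepaired = envelope$psdRepaired,
         nVarieties = envelope$nVarieties),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_envelope_json
#' @export
read_envelope_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(raw$schema, "cropideo-envelope/1"))
  env <- raw[c("names", "min", "max", "extendedMin", "extendedMax",
               "hardCapLow", "hardCapHigh", "constant", "corr",
               "psdRepaired", "nVarieties")]
  for (f in c("min", "max", "extendedMin", "extendedMax", "hardCapLow",
              "hardCapHigh"))
    env[[f]] <- setNames(as.numeric(env[[f]]), env$names)
  env$corr <- as.matrix(env$corr)
  dimnames(env$corr) <- NULL
  class(env) <- "cropideo_envelope"
  env
}
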