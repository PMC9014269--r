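# Multivariate regression trees with surrogate splits, cost-complexity
# pruning under 10-fold cross-validation, importance statistics (VIP,
# partial R2, probability of increase, class sums) and min-max best-branch
# extraction with variety matching.

#' Tree configuration
#'
#' @param minNodeSize minimum rows in a node to attempt a split (and
#'   minimum per child).
#' @param maxDepth maximum tree depth (root = 0).
#' @param maxSurrogates surrogate splits retained per node (default 20).
#' @param standardize scale responses to unit variance before pooling
#'   their sums of squares (off by default: rescaled `[0,1]` indicators
#'   are already comparable).
#' @param minImprove minimum SS reduction (as fraction of root SS) to
#'   accept a split.
#' @return named list.
#' @export
tree_config <- function(minNodeSize = 5, maxDepth = 6, maxSurrogates = 20,
                        standardize = FALSE, minImprove = 1e-9) {
  as.list(environment())
}

# Sum of squared deviations from the column means, pooled over columns.
.ss <- function(Y) {
  if (nrow(Y) == 0) return(0)
  sum(apply(Y, 2, function(y) sum((y - mean(y))^2)))
}

# Best threshold scan for one numeric predictor: returns the split with
# maximal pooled-SS reduction honoring the minimum child size.
# Vectorized over split positions via cumulative sums.
.scan_numeric <- function(x, Y, minNode) {
  ord <- order(x)
  xs <- x[ord]
  Ys <- Y[ord, , drop = FALSE]
  n <- length(xs)
  cs <- apply(Ys, 2, cumsum)
  cs2 <- apply(Ys^2, 2, cumsum)
  tot <- cs[n, ]
  tot2 <- cs2[n, ]
  kk <- seq_len(n - 1)
  ssl <- rowSums(cs2[kk, , drop = FALSE] -
                   cs[kk, , drop = FALSE]^2 / kk)
  ssr <- rowSums(sweep(-cs2[kk, , drop = FALSE], 2, tot2, `+`) -
                   sweep(-cs[kk, , drop = FALSE], 2, tot, `+`)^2 / (n - kk))
  valid <- kk >= minNode & (n - kk) >= minNode &
    xs[kk] < xs[kk + 1] - 0 # only between distinct values
  valid <- valid & (xs[kk + 1] - xs[kk]) > 0
  if (!any(valid)) return(NULL)
  ssTot <- sum(tot2 - tot^2 / n)
  red <- ssTot - (ssl + ssr)
  red[!valid] <- -Inf
  k <- which.max(red)
  list(threshold = (xs[k] + xs[k + 1]) / 2, reduction = red[k],
       leftCount = k)
}

# Categorical predictors are handled by ordering categories by the mean of
# the pooled response and scanning that ordering (exact for a single
# response; the standard CART device for multivariate ones).
.encode_predictor <- function(x, Y) {
  if (is.numeric(x)) return(list(x = x, levels = NULL))
  f <- as.factor(x)
  m <- tapply(rowMeans(Y), f, mean)
  ranks <- rank(m, ties.method = "first")
  list(x = as.numeric(ranks[as.character(f)]), levels = names(m),
       order = names(sort(m)))
}

# Surrogate search: thresholds on other predictors that reproduce the
# primary routing; kept while raw agreement beats the go-with-majority
# baseline.
.find_surrogates <- function(X, enc, goesLeft, primary, maxSurrogates,
                             minAgree) {
  n <- length(goesLeft)
  base <- max(sum(goesLeft), n - sum(goesLeft)) / n
  out <- list()
  for (j in seq_along(X)) {
    if (j == primary) next
    xj <- enc[[j]]$x
    ux <- sort(unique(xj))
    if (length(ux) < 2) next
    cand <- (ux[-1] + ux[-length(ux)]) / 2
    best <- NULL
    for (th in cand) {
      for (dir in c("left", "right")) {
        match_ <- if (dir == "left") (xj < th) == goesLeft else
          (xj >= th) == goesLeft
        agree <- mean(match_)
        if (is.null(best) || agree > best$agreement)
          best <- list(predictor = names(X)[j], threshold = th,
                       direction = dir, agreement = agree,
                       levels = enc[[j]]$levels)
      }
    }
    if (!is.null(best) && best$agreement > base + 1e-12)
      out[[length(out) + 1L]] <- best
  }
  if (!length(out)) return(list())
  out <- out[order(-vapply(out, `[[`, numeric(1), "agreement"))]
  head(out, maxSurrogates)
}

#' Grow a multivariate regression tree
#'
#' Greedy binary recursive partitioning minimizing the within-child sum of
#' squares pooled over the response columns. Numeric splits are placed at
#' midpoints between consecutive distinct values; categorical predictors
#' are scanned along the category ordering by mean response. Each split
#' stores up to `maxSurrogates` surrogate splits ranked by raw agreement
#' (fraction of rows routed identically), retained only while they beat
#' the go-with-majority baseline; rows missing the primary predictor are
#' routed by the best available surrogate, else with the majority. Ties in
#' the split search break toward the lower predictor index, then the
#' lower threshold, so builds are deterministic.
#'
#' @param X predictor data frame (numeric or categorical columns).
#' @param Y response matrix/data frame (numeric, no missing values).
#' @param config see [tree_config()].
#' @return object of class `cropideo_tree`.
#' @export
grow_tree <- function(X, Y, config = tree_config()) {
  X <- as.data.frame(X)
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("missing responses are not allowed")
  storage.mode(Y) <- "double"
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  Yw <- Y
  if (config$standardize) {
    sds <- apply(Yw, 2, sd)
    sds[sds < 1e-12] <- 1
    Yw <- sweep(Yw, 2, sds, `/`)
  }
  n <- nrow(X)
  rootSS <- .ss(Yw)
  nodes <- list()
  newNode <- function(parent, depth, rows) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, depth = depth,
                         rows = rows, n = length(rows),
                         share = length(rows) / n,
                         mean = colMeans(Y[rows, , drop = FALSE]),
                         ss = .ss(Yw[rows, , drop = FALSE]),
                         split = NULL, surrogates = list(),
                         children = c(NA_integer_, NA_integer_),
                         leaf = TRUE)
    id
  }
  grow <- function(id) {
    nd <- nodes[[id]]
    if (nd$depth >= config$maxDepth || nd$n < 2 * config$minNodeSize ||
        nd$ss <= config$minImprove * max(rootSS, 1e-300)) return()
    rows <- nd$rows
    Ysub <- Yw[rows, , drop = FALSE]
    enc <- lapply(X, function(col) .encode_predictor(col[rows], Ysub))
    best <- NULL
    for (j in seq_along(X)) {
      xj <- enc[[j]]$x
      if (anyNA(xj)) next
      sc <- .scan_numeric(xj, Ysub, config$minNodeSize)
      if (is.null(sc)) next
      if (is.null(best) || sc$reduction > best$reduction + 1e-12 ||
          (abs(sc$reduction - best$reduction) <= 1e-12 &&
           (j < best$j || (j == best$j && sc$threshold < best$threshold)))) {
        best <- c(sc, list(j = j))
      }
    }
    if (is.null(best) ||
        best$reduction <= config$minImprove * max(rootSS, 1e-300)) return()
    j <- best$j
    xj <- enc[[j]]$x
    goesLeft <- xj < best$threshold
    lvl <- enc[[j]]$levels
    split <- list(predictor = names(X)[j], threshold = best$threshold,
                  reduction = best$reduction, direction = "left",
                  levels = lvl, leftSet = NULL)
    if (!is.null(lvl)) {
      # categories routed left under the encoded ordering threshold
      split$leftSet <- enc[[j]]$order[sort(unique(xj[goesLeft]))]
    }
    surro <- .find_surrogates(X[rows, , drop = FALSE], enc, goesLeft, j,
                              config$maxSurrogates, NULL)
    lid <- newNode(id, nd$depth + 1L, rows[goesLeft])
    rid <- newNode(id, nd$depth + 1L, rows[!goesLeft])
    nodes[[id]]$split <<- split
    nodes[[id]]$surrogates <<- surro
    nodes[[id]]$children <<- c(lid, rid)
    nodes[[id]]$leaf <<- FALSE
    grow(lid)
    grow(rid)
  }
  root <- newNode(NA_integer_, 0L, seq_len(n))
  grow(root)
  leafSS <- sum(vapply(nodes, function(nd)
    if (nd$leaf) nd$ss else 0, numeric(1)))
  tree <- list(nodes = nodes, responseNames = colnames(Y), X = X, Y = Y,
               Yw = Yw, config = config, rootSS = rootSS,
               resubR2 = if (rootSS > 0) 1 - leafSS / rootSS else 0,
               cvR2 = NA_real_)
  class(tree) <- "cropideo_tree"
  tree
}

#' @export
print.cropideo_tree <- function(x, ...) {
  nl <- sum(vapply(x$nodes, `[[`, logical(1), "leaf"))
  cat("<cropideo_tree>", length(x$nodes), "nodes,", nl, "leaves; R2 =",
      round(x$resubR2, 3),
      if (!is.na(x$cvR2)) paste0("(cv ", round(x$cvR2, 3), ")"), "\n")
  invisible(x)
}

# Route data rows through the tree; returns the leaf id per row. Missing
# primary predictors fall back to the best surrogate, then the majority.
.route <- function(tree, X) {
  n <- nrow(X)
  out <- integer(n)
  routeOne <- function(i) {
    id <- 1L
    repeat {
      nd <- tree$nodes[[id]]
      if (nd$leaf) return(id)
      sp <- nd$split
      v <- X[[sp$predictor]][i]
      goLeft <- NA
      if (!is.na(v) && is.null(sp$levels)) {
        goLeft <- v < sp$threshold
      } else if (!is.na(v)) {
        goLeft <- as.character(v) %in% sp$leftSet
      }
      if (is.na(goLeft)) {
        for (su in nd$surrogates) {
          w <- X[[su$predictor]][i]
          if (is.na(w)) next
          wx <- if (is.null(su$levels)) w else
            match(as.character(w), su$levels)
          goLeft <- if (su$direction == "left") wx < su$threshold else
            wx >= su$threshold
          break
        }
      }
      if (is.na(goLeft)) {
        nL <- tree$nodes[[nd$children[1]]]$n
        nR <- tree$nodes[[nd$children[2]]]$n
        goLeft <- nL >= nR
      }
      id <- nd$children[if (goLeft) 1 else 2]
    }
  }
  for (i in seq_len(n)) out[i] <- routeOne(i)
  out
}

#' Predict node-mean responses
#'
#' @param object a `cropideo_tree`.
#' @param newdata predictor data frame (defaults to training data).
#' @param ... unused.
#' @return matrix of leaf mean vectors, one row per input row.
#' @export
predict.cropideo_tree <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$X
  ids <- .route(object, newdata)
  k <- length(object$responseNames)
  out <- vapply(ids, function(id) object$nodes[[id]]$mean, numeric(k))
  out <- if (k == 1) matrix(out, ncol = 1) else t(out)
  colnames(out) <- object$responseNames
  out
}

# ---- cost-complexity pruning -------------------------------------------

# Collapse the subtree under `id` into a leaf (in place on a node list).
.collapse <- function(nodes, id) {
  sub <- id
  queue <- id
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    ch <- nodes[[cur]]$children
    ch <- ch[!is.na(ch)]
    sub <- c(sub, ch)
    queue <- c(queue, ch)
  }
  drop <- setdiff(sub, id)
  nodes[[id]]$leaf <- TRUE
  nodes[[id]]$split <- NULL
  nodes[[id]]$surrogates <- list()
  nodes[[id]]$children <- c(NA_integer_, NA_integer_)
  for (d in drop) nodes[[d]]$pruned <- TRUE
  nodes
}

# Leaf error and leaf count of the subtree rooted at id.
.subtree_stats <- function(nodes, id) {
  nd <- nodes[[id]]
  if (nd$leaf) return(c(ss = nd$ss, leaves = 1))
  l <- .subtree_stats(nodes, nd$children[1])
  r <- .subtree_stats(nodes, nd$children[2])
  c(ss = unname(l["ss"] + r["ss"]), leaves = unname(l["leaves"] +
                                                      r["leaves"]))
}

# Weakest-link cost-complexity sequence: returns data frame of alpha
# values and, per step, the node ids collapsed up to that alpha.
.alpha_path <- function(tree) {
  nodes <- tree$nodes
  alive <- function(id) is.null(nodes[[id]]$pruned)
  path <- list(list(alpha = 0, collapsed = integer(0)))
  collapsedAll <- integer(0)
  repeat {
    internal <- which(vapply(nodes, function(nd)
      !nd$leaf && is.null(nd$pruned), logical(1)))
    if (!length(internal)) break
    g <- vapply(internal, function(id) {
      st <- .subtree_stats(nodes, id)
      (nodes[[id]]$ss - st["ss"]) / max(st["leaves"] - 1, 1)
    }, numeric(1))
    gmin <- min(g)
    weakest <- internal[g <= gmin + 1e-12]
    for (idc in weakest) if (is.null(nodes[[idc]]$pruned) &&
                             !nodes[[idc]]$leaf)
      nodes <- .collapse(nodes, idc)
    collapsedAll <- c(collapsedAll, weakest)
    path[[length(path) + 1L]] <- list(alpha = gmin,
                                      collapsed = collapsedAll)
  }
  path
}

# Prune a tree copy at complexity alpha using its own path (which may be
# precomputed and passed in to avoid repeated traversals).
.prune_at <- function(tree, alpha, path = NULL) {
  if (is.null(path)) path <- .alpha_path(tree)
  alphas <- vapply(path, `[[`, numeric(1), "alpha")
  k <- max(which(alphas <= alpha + 1e-12))
  ids <- path[[k]]$collapsed
  nodes <- tree$nodes
  for (id in ids) if (!nodes[[id]]$leaf) nodes <- .collapse(nodes, id)
  tree$nodes <- nodes
  leafSS <- sum(vapply(nodes, function(nd)
    if (nd$leaf && is.null(nd$pruned)) nd$ss else 0, numeric(1)))
  tree$resubR2 <- if (tree$rootSS > 0) 1 - leafSS / tree$rootSS else 0
  tree
}

#' Prune a tree by cross-validated cost complexity
#'
#' Builds the weakest-link complexity path of the fitted tree, estimates
#' the out-of-sample pooled squared error of each complexity value by
#' `folds`-fold cross-validation (fold trees are grown with the same
#' configuration and pruned at the geometric-mean test complexities, the
#' standard CART device), selects the complexity minimizing the
#' cross-validated error, and returns the tree pruned there with its
#' cross-validated R2. Fold assignment is deterministic under `seed`.
#'
#' @param tree a `cropideo_tree`.
#' @param folds number of folds (>= 2, <= n).
#' @param seed integer seed for fold assignment.
#' @return the pruned `cropideo_tree` with `cvR2` set.
#' @export
prune_cv <- function(tree, folds = 10, seed = 1) {
  if (folds < 2) stop("folds must be >= 2")
  n <- nrow(tree$X)
  if (n < folds) stop("need n >= folds")
  path <- .alpha_path(tree)
  alphas <- vapply(path, `[[`, numeric(1), "alpha")
  # test points: geometric means of successive alphas, plus the endpoints
  # (0 = full tree, beyond the last collapse = root)
  atest <- if (length(alphas) == 1) 0 else
    c(0, sqrt(alphas[-1] * pmax(alphas[-length(alphas)],
                                alphas[-1] * 1e-3)), Inf)
  atest <- unique(atest)
  fold <- with_stream(seed, "cvfolds",
                      sample(rep_len(seq_len(folds), n)))
  err <- matrix(0, length(atest), 1)
  for (f in seq_len(folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    ft <- grow_tree(tree$X[tr, , drop = FALSE],
                    tree$Yw[tr, , drop = FALSE], tree$config)
    # complexities are compared on the relative (cp = alpha / root SS)
    # scale so fold trees prune consistently with the full tree
    scale <- if (tree$rootSS > 0) ft$rootSS / tree$rootSS else 1
    fpath <- .alpha_path(ft)
    for (ai in seq_along(atest)) {
      pt <- .prune_at(ft, atest[ai] * scale, path = fpath)
      pred <- predict.cropideo_tree(pt, tree$X[te, , drop = FALSE])
      err[ai, 1] <- err[ai, 1] +
        sum((tree$Yw[te, , drop = FALSE] - pred)^2)
    }
  }
  bestA <- atest[which.min(err[, 1])]
  out <- .prune_at(tree, bestA)
  out$cvR2 <- if (tree$rootSS > 0) 1 - min(err[, 1]) / tree$rootSS else 0
  out$cvErr <- err[, 1]
  out$cvAlphas <- atest
  out$alpha <- bestA
  out
}

# ---- importance ---------------------------------------------------------

#' Importance statistics of a fitted tree
#'
#' VIP accumulates each split's SS improvement to the primary predictor
#' and, weighted by raw agreement, to each surrogate. Relative VIPs are
#' rescaled to sum to 1; the partial R2 of a predictor is its relative VIP
#' times the tree's (cross-validated, if available) R2; the probability of
#' increase is the node-size-weighted share of splits (primary or
#' surrogate) in which the child holding the higher predictor values has
#' the higher mean response; class sums add partial R2 over the predictors
#' of each declared class.
#'
#' @param tree a fitted (ideally pruned) `cropideo_tree`.
#' @param classes optional named list mapping class names to predictor
#'   name vectors.
#' @return list with `table` (per predictor: VIP, relVIP, partialR2,
#'   probIncrease) and `classes` (summed partial R2 per class).
#' @export
tree_importance <- function(tree, classes = NULL) {
  if (is.null(tree$nodes)) stop("unfitted tree")
  preds <- names(tree$X)
  vip <- setNames(numeric(length(preds)), preds)
  wUp <- setNames(numeric(length(preds)), preds)
  wTot <- setNames(numeric(length(preds)), preds)
  for (nd in tree$nodes) {
    if (nd$leaf || !is.null(nd$pruned)) next
    imp <- nd$split$reduction
    mL <- mean(tree$nodes[[nd$children[1]]]$mean)
    mR <- mean(tree$nodes[[nd$children[2]]]$mean)
    # primary: left child holds the lower predictor values
    p <- nd$split$predictor
    vip[p] <- vip[p] + imp
    wTot[p] <- wTot[p] + nd$n
    if (mR > mL) wUp[p] <- wUp[p] + nd$n
    else if (mR == mL) wUp[p] <- wUp[p] + nd$n / 2
    for (su in nd$surrogates) {
      q <- su$predictor
      vip[q] <- vip[q] + su$agreement * imp
      wTot[q] <- wTot[q] + nd$n
      higherRight <- su$direction == "left"
      mHigh <- if (higherRight) mR else mL
      mLow <- if (higherRight) mL else mR
      if (mHigh > mLow) wUp[q] <- wUp[q] + nd$n
      else if (mHigh == mLow) wUp[q] <- wUp[q] + nd$n / 2
    }
  }
  tot <- sum(vip)
  rel <- if (tot > 0) vip / tot else vip
  r2 <- if (!is.na(tree$cvR2)) tree$cvR2 else tree$resubR2
  tab <- data.frame(predictor = preds, VIP = unname(vip),
                    relVIP = unname(rel),
                    partialR2 = unname(rel * r2),
                    probIncrease = unname(ifelse(wTot > 0, wUp / wTot,
                                                 NA_real_)))
  cls <- NULL
  if (!is.null(classes)) {
    cls <- data.frame(
      class = names(classes),
      partialR2 = vapply(classes, function(ps)
        sum(tab$partialR2[tab$predictor %in% ps]), numeric(1)))
    rownames(cls) <- NULL
  }
  list(table = tab, classes = cls, R2 = r2)
}

# ---- branches -----------------------------------------------------------

# Rule path from root to a leaf.
.branch_rules <- function(tree, leafId) {
  rules <- list()
  id <- leafId
  while (!is.na(tree$nodes[[id]]$parent)) {
    par <- tree$nodes[[id]]$parent
    nd <- tree$nodes[[par]]
    isLeft <- nd$children[1] == id
    sp <- nd$split
    rules[[length(rules) + 1L]] <- if (is.null(sp$levels)) {
      data.frame(predictor = sp$predictor,
                 comparator = if (isLeft) "<" else ">=",
                 threshold = sp$threshold,
                 set = NA_character_,
                 rank = nd$depth + 1L)
    } else {
      inSet <- if (isLeft) sp$leftSet else setdiff(sp$levels, sp$leftSet)
      data.frame(predictor = sp$predictor, comparator = "in",
                 threshold = NA_real_,
                 set = paste(inSet, collapse = "|"),
                 rank = nd$depth + 1L)
    }
    id <- par
  }
  if (!length(rules)) return(data.frame(
    predictor = character(0), comparator = character(0),
    threshold = numeric(0), set = character(0), rank = integer(0)))
  out <- do.call(rbind, rev(rules))
  rownames(out) <- NULL
  out
}

#' Extract the best branches of a fitted tree
#'
#' Leaves are ordered by their mean response (univariate mode) or by the
#' minimum of their per-indicator means (multivariate mode), descending;
#' the top `k` are returned as branches with the full rule path (rule rank
#' = depth of the rule's node). In multivariate mode the first branch
#' satisfies the min-max condition `min_i T_bi > max_{b'} min_i T_b'i`
#' against all other leaves by construction of the ordering.
#'
#' @param tree a fitted `cropideo_tree`.
#' @param k number of branches (all leaves if larger).
#' @param responseMode `"multivariate"` (min over indicators) or
#'   `"univariate"` (mean response).
#' @return list of branches: each has `rules`, `n`, `share`, `mean`
#'   (`T_b` vector), `score`.
#' @export
select_best_branches <- function(tree, k = 3,
                                 responseMode = c("multivariate",
                                                  "univariate")) {
  responseMode <- match.arg(responseMode)
  leaves <- which(vapply(tree$nodes, function(nd)
    nd$leaf && is.null(nd$pruned), logical(1)))
  score <- vapply(leaves, function(id) {
    m <- tree$nodes[[id]]$mean
    if (responseMode == "multivariate") min(m) else mean(m)
  }, numeric(1))
  ord <- order(-score)
  take <- head(ord, min(k, length(leaves)))
  lapply(take, function(i) {
    id <- leaves[i]
    nd <- tree$nodes[[id]]
    list(rules = .branch_rules(tree, id), n = nd$n, share = nd$share,
         mean = nd$mean, score = score[i], leafId = id)
  })
}

#' Resolve a variety parameter by rule name
#'
#' Accepts scalar parameter names (`harvestIndex`), early/mid/late
#' summaries (`LBR_late`, also written `LBRlate`), and explicit stage
#' entries (`LBR.s8`).
#'
#' @param variety a `cropideo_variety`.
#' @param name parameter name.
#' @return numeric value, or `NA` if the name cannot be resolved.
#' @export
variety_param_value <- function(variety, name) {
  if (name %in% SCALAR_PARAMS) return(as.numeric(variety[[name]]))
  m <- regmatches(name, regexec("^([A-Za-z_]+?)[._]?(early|mid|late)$",
                                name))[[1]]
  if (length(m) == 3 && m[2] %in% STAGE_PARAMS)
    return(unname(stage_summary(variety$stages[[m[2]]])[m[3]]))
  m <- regmatches(name, regexec("^([A-Za-z_]+)\\.s([0-9]+)$", name))[[1]]
  if (length(m) == 3 && m[2] %in% STAGE_PARAMS)
    return(variety$stages[[m[2]]][as.integer(m[3]) + 1L])
  NA_real_
}

#' Match varieties against a branch's parameter rules
#'
#' A variety matches when every variety-parameter rule of the branch is
#' satisfied by its parameter values; technique and situation rules
#' (predictors without the `pea.` prefix) are ignored. Contradictory
#' parameter rules flag the branch infeasible (no matches). Unknown
#' parameter names are an error.
#'
#' @param branch a branch from [select_best_branches()].
#' @param varieties named list of `cropideo_variety`.
#' @param prefix prefix marking variety-parameter predictors.
#' @return character vector of matching variety names; attribute
#'   `infeasible` set when the parameter rules contradict.
#' @export
match_varieties <- function(branch, varieties, prefix = "pea.") {
  rules <- branch$rules
  isPar <- startsWith(rules$predictor, prefix)
  rules <- rules[isPar, , drop = FALSE]
  if (!nrow(rules)) return(names(varieties))
  rules$param <- substring(rules$predictor, nchar(prefix) + 1)
  bad <- vapply(rules$param, function(p)
    is.na(variety_param_value(varieties[[1]], p)), logical(1))
  if (any(bad))
    stop("unknown parameter name(s): ",
         paste(unique(rules$param[bad]), collapse = ", "))
  # feasibility: lower bounds must stay below upper bounds per parameter
  infeasible <- FALSE
  for (p in unique(rules$param)) {
    r <- rules[rules$param == p, ]
    lo <- suppressWarnings(max(r$threshold[r$comparator == ">="],
                               -Inf, na.rm = TRUE))
    hi <- suppressWarnings(min(r$threshold[r$comparator == "<"],
                               Inf, na.rm = TRUE))
    if (lo >= hi) infeasible <- TRUE
  }
  if (infeasible) {
    out <- character(0)
    attr(out, "infeasible") <- TRUE
    return(out)
  }
  ok <- vapply(varieties, function(v) {
    all(vapply(seq_len(nrow(rules)), function(i) {
      val <- variety_param_value(v, rules$param[i])
      switch(rules$comparator[i],
             "<" = val < rules$threshold[i],
             ">=" = val >= rules$threshold[i],
             "in" = TRUE)
    }, logical(1)))
  }, logical(1))
  names(varieties)[ok]
}

#' Human-readable branch rules
#'
#' @param branch a branch from [select_best_branches()].
#' @return character vector, one rule per line.
#' @export
format_branch <- function(branch) {
  r <- branch$rules
  if (!nrow(r)) return("(root: no rules)")
  vapply(seq_len(nrow(r)), function(i)
    if (r$comparator[i] == "in")
      sprintf("[%d] %s in {%s}", r$rank[i], r$predictor[i], r$set[i])
    else sprintf("[%d] %s %s %.4g", r$rank[i], r$predictor[i],
                 r$comparator[i], r$threshold[i]),
    character(1))
}

#' Dump a tree to JSON
#'
#' Full node dump (splits, surrogates, means, shares) for archival or
#' external rendering.
#'
#' @param tree a `cropideo_tree`.
#' @param path file path.
#' @export
write_tree_json <- function(tree, path) {
  nodes <- lapply(tree$nodes, function(nd) {
    if (!is.null(nd$pruned)) return(NULL)
    list(id = nd$id, parent = nd$parent, depth = nd$depth, n = nd$n,
         share = nd$share, mean = as.list(nd$mean), leaf = nd$leaf,
         split = nd$split,
         surrogates = lapply(nd$surrogates, function(su)
           su[c("predictor", "threshold", "direction", "agreement")]),
         children = nd$children)
  })
  jsonlite::write_json(
    list(schema = "cropideo-tree/1", responses = tree$responseNames,
         resubR2 = tree$resubR2, cvR2 = tree$cvR2,
         nodes = Filter(Negate(is.null), nodes)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
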