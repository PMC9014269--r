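# Exhaustive split search over all predictors and midpoints (oracle).
brute_best_split <- function(X, Y, minNode) {
  ssf <- function(M) sum(apply(M, 2, function(v) sum((v - mean(v))^2)))
  best <- -Inf; arg <- NULL
  rows <- seq_len(nrow(X))
  for (j in seq_along(X)) {
    xs <- sort(unique(X[[j]]))
    if (length(xs) < 2) next
    for (k in seq_len(length(xs) - 1)) {
      th <- (xs[k] + xs[k + 1]) / 2
      L <- rows[X[[j]] < th]; R <- rows[X[[j]] >= th]
      if (length(L) < minNode || length(R) < minNode) next
      red <- ssf(Y) - ssf(Y[L, , drop = FALSE]) - ssf(Y[R, , drop = FALSE])
      if (red > best) { best <- red; arg <- c(j, th) }
    }
  }
  list(reduction = best, predictor = arg[1], threshold = arg[2])
}

test_that("step data yield a single exact split with R2 = 1", {
  set.seed(5)
  x <- runif(60, 0, 6)
  y <- as.numeric(x > 3)
  tr <- grow_tree(data.frame(x1 = x), cbind(y = y))
  sp <- tr$nodes[[1]]$split
  expect_equal(sp$predictor, "x1")
  xs <- sort(x)
  expect_true(sp$threshold > max(xs[xs <= 3]) &&
                sp$threshold <= min(xs[xs > 3]))
  expect_equal(tr$resubR2, 1)
  # constant responses: a single leaf, R2 = 0
  tc <- grow_tree(data.frame(x1 = x), cbind(y = rep(2, 60)))
  expect_equal(length(tc$nodes), 1)
  expect_true(tc$nodes[[1]]$leaf)
  expect_equal(tc$resubR2, 0)
})

test_that("chosen splits equal the exhaustive-enumeration oracle", {
  for (sd in c(5, 11, 17)) {
    set.seed(sd)
    n <- 50
    X <- data.frame(a = runif(n), b = runif(n), c = runif(n))
    Y <- cbind(y1 = runif(n), y2 = runif(n))
    tr <- grow_tree(X, Y, tree_config(minNodeSize = 5, maxDepth = 2))
    # root and both children against the oracle
    for (id in c(1L, tr$nodes[[1]]$children)) {
      nd <- tr$nodes[[id]]
      if (is.na(id) || nd$leaf) next
      o <- brute_best_split(X[nd$rows, , drop = FALSE],
                            Y[nd$rows, , drop = FALSE], 5)
      expect_equal(nd$split$reduction, o$reduction, tolerance = 1e-10)
    }
  }
})

test_that("univariate splits agree with rpart", {
  skip_if_not_installed("rpart")
  set.seed(5)
  x <- runif(60, 0, 6)
  y <- as.numeric(x > 3) + rnorm(60, 0, 0.1)
  tr <- grow_tree(data.frame(x1 = x), cbind(y = y),
                  tree_config(minNodeSize = 5, maxDepth = 1))
  rp <- rpart::rpart(y ~ x1, data = data.frame(x1 = x, y = y),
                     method = "anova",
                     control = rpart::rpart.control(
                       minsplit = 10, minbucket = 5, cp = 0,
                       maxdepth = 1, xval = 0))
  expect_equal(tr$nodes[[1]]$split$threshold,
               unname(rp$splits[1, "index"]), tolerance = 1e-9)
})

test_that("tree structure is invariant to monotone predictor transforms", {
  set.seed(9)
  n <- 80
  X <- data.frame(a = runif(n), b = runif(n))
  Y <- cbind(y = X$a * 2 + as.numeric(X$b > 0.6) + rnorm(n, 0, 0.2))
  t1 <- grow_tree(X, Y, tree_config(minNodeSize = 8, maxDepth = 3))
  X2 <- data.frame(a = exp(3 * X$a), b = X$b^3)
  t2 <- grow_tree(X2, Y, tree_config(minNodeSize = 8, maxDepth = 3))
  ids1 <- cropideo:::.route(t1, X)
  ids2 <- cropideo:::.route(t2, X2)
  # identical partition of rows into leaves
  expect_equal(as.integer(factor(ids1, levels = unique(ids1))),
               as.integer(factor(ids2, levels = unique(ids2))))
  for (k in seq_along(t1$nodes)) {
    expect_equal(t1$nodes[[k]]$split$predictor,
                 t2$nodes[[k]]$split$predictor)
    expect_equal(t1$nodes[[k]]$n, t2$nodes[[k]]$n)
  }
})

test_that("pruning: cvR2 never exceeds resubstitution R2; signal survives,
           noise collapses", {
  set.seed(5)
  x <- runif(60, 0, 6)
  tr <- grow_tree(data.frame(x1 = x), cbind(y = as.numeric(x > 3)))
  ps <- prune_cv(tr, folds = 10, seed = 3)
  expect_equal(sum(vapply(ps$nodes, function(n)
    n$leaf && is.null(n$pruned), logical(1))), 2)
  expect_equal(ps$cvR2, 1, tolerance = 1e-9)
  for (sd in c(2, 7)) {
    set.seed(sd)
    Xn <- data.frame(a = runif(80), b = runif(80))
    tn <- grow_tree(Xn, cbind(y = rnorm(80)),
                    tree_config(minNodeSize = 5, maxDepth = 4))
    pn <- prune_cv(tn, folds = 10, seed = sd)
    expect_lte(pn$cvR2, pn$resubR2 + 1e-9)
  }
  expect_error(prune_cv(tr, folds = 1), "folds")
})

test_that("importance: relative VIPs sum to one, monotone responses give
           probability 1 or 0", {
  set.seed(3)
  x <- sort(runif(60))
  z <- runif(60)
  tm <- prune_cv(grow_tree(data.frame(x = x, z = z),
                           cbind(y = 2 * x),
                           tree_config(minNodeSize = 5, maxDepth = 3)),
                 seed = 1)
  im <- tree_importance(tm)
  expect_equal(sum(im$table$relVIP), 1, tolerance = 1e-9)
  expect_equal(im$table$probIncrease[im$table$predictor == "x"], 1)
  td <- prune_cv(grow_tree(data.frame(x = x, z = z),
                           cbind(y = -2 * x),
                           tree_config(minNodeSize = 5, maxDepth = 3)),
                 seed = 1)
  id <- tree_importance(td)
  expect_equal(id$table$probIncrease[id$table$predictor == "x"], 0)
  # single effective predictor: relVIP concentrates, partial R2 = relVIP * cvR2
  expect_equal(im$table$partialR2, im$table$relVIP * im$R2,
               tolerance = 1e-12)
  expect_error(tree_importance(list()), "unfitted")
})

test_that("a perfect surrogate earns importance without ever splitting", {
  set.seed(8)
  xd <- runif(60)
  td <- grow_tree(data.frame(p = xd, q = xd),
                  cbind(y = as.numeric(xd > 0.5)),
                  tree_config(minNodeSize = 5, maxDepth = 1))
  nd <- td$nodes[[1]]
  expect_equal(nd$split$predictor, "p")  # tie broken to lower index
  expect_equal(length(nd$surrogates), 1)
  expect_equal(nd$surrogates[[1]]$agreement, 1)
  im <- tree_importance(td)
  expect_gt(im$table$VIP[im$table$predictor == "q"], 0)
  expect_equal(im$table$VIP[im$table$predictor == "q"],
               im$table$VIP[im$table$predictor == "p"])
})

test_that("class-wise partial R2 sums over member predictors", {
  set.seed(4)
  n <- 90
  X <- data.frame(a1 = runif(n), a2 = runif(n), b1 = runif(n))
  Y <- cbind(y = 2 * X$a1 + as.numeric(X$a2 > 0.5) + rnorm(n, 0, 0.1))
  pt <- prune_cv(grow_tree(X, Y, tree_config(minNodeSize = 8,
                                             maxDepth = 3)), seed = 2)
  im <- tree_importance(pt, classes = list(A = c("a1", "a2"), B = "b1"))
  expect_equal(sum(im$classes$partialR2),
               sum(im$table$partialR2), tolerance = 1e-12)
  expect_gt(im$classes$partialR2[im$classes$class == "A"],
            im$classes$partialR2[im$classes$class == "B"])
})

test_that("multivariate best branch satisfies the min-max rule", {
  set.seed(12)
  n <- 120
  X <- data.frame(a = runif(n), b = runif(n), c = runif(n))
  Y <- cbind(y1 = runif(n), y2 = runif(n))
  tr <- grow_tree(X, Y, tree_config(minNodeSize = 6, maxDepth = 4))
  brs <- select_best_branches(tr, k = 3, responseMode = "multivariate")
  leaves <- Filter(function(nd) nd$leaf && is.null(nd$pruned), tr$nodes)
  mins <- vapply(leaves, function(nd) min(nd$mean), numeric(1))
  expect_equal(min(brs[[1]]$mean), max(mins))
  expect_gt(min(brs[[1]]$mean),
            max(mins[-which.max(mins)]))
  # ordering is descending in the min-score
  scores <- vapply(brs, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 1e-12))
  # k larger than the number of leaves returns all leaves
  expect_length(select_best_branches(tr, k = 999), length(leaves))
  # rule ranks equal the depth of the rule's node
  expect_equal(brs[[1]]$rules$rank, seq_len(nrow(brs[[1]]$rules)))
})

test_that("univariate branch ordering is by leaf mean", {
  set.seed(5)
  x <- runif(90)
  tr <- grow_tree(data.frame(x = x), cbind(y = x),
                  tree_config(minNodeSize = 10, maxDepth = 2))
  brs <- select_best_branches(tr, k = 10, responseMode = "univariate")
  means <- vapply(brs, function(b) unname(b$mean), numeric(1))
  expect_true(all(diff(means) <= 1e-12))
})

test_that("variety matching follows the branch's parameter rules", {
  vs <- pea_reference_varieties()
  br <- list(rules = data.frame(
    predictor = "pea.harvestIndex", comparator = ">=", threshold = 0.5,
    set = NA_character_, rank = 1L))
  expect_setequal(match_varieties(br, vs),
                  c("Kayanne", "Enduro", "Isard"))
  # empty rule list matches everything
  br0 <- list(rules = data.frame(predictor = character(0),
                                 comparator = character(0),
                                 threshold = numeric(0),
                                 set = character(0), rank = integer(0)))
  expect_setequal(match_varieties(br0, vs), names(vs))
  # technique rules are ignored for matching
  brT <- list(rules = data.frame(
    predictor = c("pea_density", "pea.harvestIndex"),
    comparator = c(">=", ">="), threshold = c(200, 0.5),
    set = NA_character_, rank = 1:2))
  expect_setequal(match_varieties(brT, vs),
                  c("Kayanne", "Enduro", "Isard"))
  # contradictory parameter rules: infeasible, no matches
  brX <- list(rules = data.frame(
    predictor = rep("pea.harvestIndex", 2),
    comparator = c("<", ">="), threshold = c(0.3, 0.5),
    set = NA_character_, rank = 1:2))
  out <- match_varieties(brX, vs)
  expect_length(out, 0)
  expect_true(attr(out, "infeasible"))
  # unknown parameter names are an error
  brU <- list(rules = data.frame(
    predictor = "pea.noSuchThing", comparator = "<", threshold = 1,
    set = NA_character_, rank = 1L))
  expect_error(match_varieties(brU, vs), "noSuchThing")
})

test_that("stage-summary rule names resolve against varieties", {
  v <- pea_reference_varieties()$Kayanne
  expect_equal(variety_param_value(v, "harvestIndex"), 0.52)
  expect_equal(variety_param_value(v, "LBR_late"),
               unname(stage_summary(v$stages$LBR)["late"]))
  expect_equal(variety_param_value(v, "LBRlate"),
               variety_param_value(v, "LBR_late"))
  expect_equal(variety_param_value(v, "HM.s4"), v$stages$HM[5])
  expect_true(is.na(variety_param_value(v, "bogus")))
})

test_that("tree JSON dump writes live nodes with splits and surrogates", {
  set.seed(8)
  xd <- runif(60)
  td <- grow_tree(data.frame(p = xd, q = xd),
                  cbind(y = as.numeric(xd > 0.5)),
                  tree_config(minNodeSize = 5, maxDepth = 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_tree_json(td, f)
  js <- jsonlite::read_json(f)
  expect_equal(js$schema, "cropideo-tree/1")
  expect_length(js$nodes, 3)
  expect_equal(js$nodes[[1]]$split$predictor, "p")
  expect_equal(js$nodes[[1]]$surrogates[[1]]$agreement, 1)
})
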