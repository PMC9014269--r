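test_that("noise-free potential-morphology fits recover the truth exactly", {
  v <- toy_variety()
  g <- gen_garden_plot(v, stages = 6, nPerStage = 6, shadeLevels = 0,
                       noiseCV = 0, seed = 1)
  fit <- fit_potential_morphology(g)
  est <- setNames(fit$estimate, fit$parameter)
  expect_equal(est[["HM"]], 20, tolerance = 1e-6)
  expect_equal(est[["b_HM"]], 0.3, tolerance = 1e-6)
  expect_equal(est[["WM"]], 10, tolerance = 1e-6)
  expect_equal(est[["b_WM"]], 0.4, tolerance = 1e-6)
  expect_equal(est[["SLA"]], 150, tolerance = 1e-6)
  expect_equal(est[["LBR"]], 0.8, tolerance = 1e-6)
  expect_equal(est[["RLH"]], 0.5, tolerance = 1e-4)
  expect_equal(est[["b_RLH"]], 2, tolerance = 1e-4)
})

test_that("constant height gives a zero allometric exponent", {
  g <- gen_garden_plot(toy_variety(), stages = 6, nPerStage = 6,
                       shadeLevels = 0, noiseCV = 0, seed = 1)
  g$height <- 12  # same height regardless of biomass
  fit <- fit_potential_morphology(g)
  expect_equal(fit$estimate[fit$parameter == "b_HM"], 0, tolerance = 1e-10)
  expect_equal(fit$estimate[fit$parameter == "HM"], 12, tolerance = 1e-10)
})

test_that("fit_potential_morphology enforces its preconditions", {
  g <- gen_garden_plot(toy_variety(), stages = 6, nPerStage = 3,
                       shadeLevels = 0, noiseCV = 0, seed = 1)
  expect_error(fit_potential_morphology(g[1:2, ]), ">= 3")
  g2 <- g
  g2$aboveGroundBiomass[1] <- 0
  expect_error(fit_potential_morphology(g2), "biomass")
})

test_that("estimates are invariant to row order and duplication", {
  g <- gen_garden_plot(toy_variety(), stages = 6, nPerStage = 6,
                       shadeLevels = 0, noiseCV = 0.1, seed = 2)
  f1 <- fit_potential_morphology(g)
  f2 <- fit_potential_morphology(g[sample(nrow(g)), ])
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-10)
  f3 <- fit_potential_morphology(rbind(g, g))
  expect_equal(f1$estimate, f3$estimate, tolerance = 1e-10)
})

test_that("leaf-profile fit recovers exact and uniform profiles", {
  h <- seq(0.05, 0.95, by = 0.05)
  exact <- data.frame(relativeHeight = c(h, 1),
                      cumulativeLeafAreaFraction =
                        c(leaf_profile_cdf(h, 0.5, 2), 1))
  lp <- fit_leaf_profile(list(exact))
  expect_equal(lp$RLH, 0.5, tolerance = 1e-6)
  expect_equal(lp$b_RLH, 2, tolerance = 1e-6)
  uni <- data.frame(relativeHeight = c(h, 1),
                    cumulativeLeafAreaFraction = c(h, 1))
  lu <- fit_leaf_profile(list(uni))
  expect_equal(lu$RLH, 0.5, tolerance = 1e-6)
  expect_equal(lu$b_RLH, 1, tolerance = 1e-6)
  # asymmetric case
  asym <- data.frame(relativeHeight = c(h, 1),
                     cumulativeLeafAreaFraction =
                       c(leaf_profile_cdf(h, 0.35, 3.2), 1))
  la <- fit_leaf_profile(list(asym))
  expect_equal(la$RLH, 0.35, tolerance = 1e-5)
  expect_equal(la$b_RLH, 3.2, tolerance = 1e-4)
})

test_that("degenerate leaf profiles hit the shape cap with a boundary flag", {
  h <- seq(0.05, 0.95, by = 0.05)
  step <- data.frame(relativeHeight = c(h, 1),
                     cumulativeLeafAreaFraction = c(as.numeric(h >= 0.5), 1))
  ld <- fit_leaf_profile(list(step), bMax = 50)
  expect_true(ld$boundary)
  expect_lte(ld$b_RLH, 50)
})

test_that("noise-free shade-response fits recover mu exactly", {
  v <- toy_variety(mu_HM = 0.4)
  g <- gen_garden_plot(v, stages = 6, nPerStage = 5,
                       shadeLevels = c(0, 0.3, 0.6, 0.8), noiseCV = 0,
                       seed = 3)
  sh <- fit_shade_response(g)
  est <- setNames(sh$estimate, sh$parameter)
  expect_equal(est[["mu_SLA"]], 0.08, tolerance = 1e-6)
  expect_equal(est[["mu_LBR"]], 0.05, tolerance = 1e-6)
  expect_equal(est[["mu_HM"]], 0.4, tolerance = 1e-6)
  expect_equal(est[["mu_WM"]], -0.1, tolerance = 1e-6)
  expect_equal(est[["mu_RLH"]], 0.02, tolerance = 1e-4)
})

test_that("identical shaded and unshaded plants give mu = 0", {
  v <- toy_variety()
  v$stages[paste0("mu_", c("SLA", "LBR", "HM", "WM", "RLH"))] <- 0
  g <- gen_garden_plot(v, stages = 6, nPerStage = 5,
                       shadeLevels = c(0, 0.5), noiseCV = 0, seed = 1)
  sh <- fit_shade_response(g)
  expect_true(all(abs(sh$estimate) < 1e-8))
})

test_that("shade fit needs at least two shading levels", {
  g <- gen_garden_plot(toy_variety(), stages = 6, nPerStage = 5,
                       shadeLevels = 0, noiseCV = 0, seed = 1)
  expect_error(fit_shade_response(g), "rank deficiency|levels")
})

test_that("BBCH interpolation: constants, lines, clamped tails, length 11", {
  const <- expand.grid(stage = c(2, 4, 6, 8, 9), parameter = "SLA")
  const$estimate <- 120
  ic <- interpolate_bbch(const)
  expect_equal(nrow(ic), 11)
  expect_equal(ic$value, rep(120, 11))
  lin <- expand.grid(stage = c(2, 4, 6, 8, 9), parameter = "HM")
  lin$estimate <- 2 + 3 * lin$stage
  il <- interpolate_bbch(lin)
  inner <- il$stage >= 2 & il$stage <= 9
  expect_equal(il$value[inner], 2 + 3 * il$stage[inner], tolerance = 1e-6)
  # clamped outside the sampled range
  expect_equal(il$value[il$stage < 2], rep(2 + 3 * 2, 2))
  expect_equal(il$value[il$stage > 9], rep(2 + 3 * 9, 1))
  expect_error(interpolate_bbch(lin[lin$stage <= 4, ]), ">= 3")
})

test_that("full chain round-trips every preset at the sampled stages", {
  vs <- pea_reference_varieties()
  for (nm in c("Kayanne", "China", "Isard")) {
    truth <- vs[[nm]]
    g <- gen_garden_plot(truth, noiseCV = 0, seed = 1)
    fitted <- fit_variety_from_garden(g, truth)
    ft <- flatten_variety(truth)
    ff <- flatten_variety(fitted)
    idx <- grep("[.]s[2489]$", names(ft))
    rel <- abs(ff[idx] - ft[idx]) / pmax(abs(ft[idx]), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("Kayanne stage-8 LBR estimate sits in the published late window", {
  g <- gen_garden_plot(pea_reference_varieties()$Kayanne, noiseCV = 0,
                       seed = 1)
  fit <- fit_potential_morphology(g[g$stageBBCH == 8, ])
  lbr <- fit$estimate[fit$parameter == "LBR"]
  expect_true(lbr >= 0.27 && lbr <= 0.59)
  brlh <- fit$estimate[fit$parameter == "b_RLH"]
  expect_gte(brlh, 1.94 - 1e-6)
  expect_lte(brlh, 4.62 + 1e-6)
})

test_that("long-format export has one row per (stage, parameter)", {
  g <- gen_garden_plot(toy_variety(), stages = c(4, 6), nPerStage = 4,
                       noiseCV = 0, seed = 1)
  fits <- lapply(c(4, 6), function(st)
    fit_potential_morphology(g[g$stageBBCH == st, ]))
  long <- fits_to_long(fits, variety = "toy")
  expect_equal(nrow(long), 16)
  expect_setequal(unique(long$stage), c(4, 6))
  expect_true(all(c("variety", "stage", "parameter", "estimate", "se") %in%
                    names(long)))
})
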