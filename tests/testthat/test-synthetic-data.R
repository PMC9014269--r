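test_that("reference varieties carry the published per-variety values", {
  vs <- pea_reference_varieties()
  expect_length(vs, 7)
  expect_setequal(names(vs), c("Cameor", "Kayanne", "China", "DCG0449",
                               "886/1", "Enduro", "Isard"))
  k <- vs$Kayanne
  expect_equal(k$seedMass, 183)
  expect_equal(k$harvestIndex, 0.52)
  expect_equal(k$max_height, 121)
  expect_equal(k$max_width, 89)
  expect_equal(k$seasonality, "spring")
  expect_equal(k$leafType, "afila")
  expect_equal(vs$Isard$harvestIndex, 0.54)
  expect_equal(vs$Isard$max_height, 97)
  expect_equal(vs$DCG0449$seedMass, 102)
  expect_equal(vs$China$seasonality, "winter_Hr")
})

test_that("every preset stays inside the observed trait envelopes", {
  vs <- pea_reference_varieties()
  for (v in vs) {
    expect_true(v$tPhoto2 >= 15 && v$tPhoto2 <= 27)
    lbr <- stage_summary(v$stages$LBR)
    expect_true(lbr[["late"]] >= 0.27 && lbr[["late"]] <= 0.59)
    brlh <- stage_summary(v$stages$b_RLH)
    expect_true(brlh[["late"]] >= 1.94 && brlh[["late"]] <= 4.62)
    expect_true(v$PeaFloweringTT >= 846 && v$PeaFloweringTT <= 4824)
    expect_silent(validate_variety(v))
  }
})

test_that("variety validation rejects broken invariants", {
  v <- pea_reference_varieties()$Cameor
  v$g50 <- v$g0 - 1
  expect_error(validate_variety(v), "g0")
  v <- pea_reference_varieties()$Cameor
  v$stages$RLH[3] <- 1.2
  expect_error(validate_variety(v), "RLH")
  v <- pea_reference_varieties()$Cameor
  v$harvestIndex <- 1.4
  expect_error(validate_variety(v), "harvestIndex")
})

test_that("shade factor is 1 at mu = 0 or s = 0 and monotone with sign(mu)", {
  s <- seq(0, 0.99, by = 0.11)
  expect_equal(shade_factor(0, s), rep(1, length(s)))
  expect_equal(shade_factor(0.3, 0), 1)
  up <- shade_factor(0.5, s)
  expect_true(all(diff(up) > 0))
  down <- shade_factor(-0.5, s)
  expect_true(all(diff(down) < 0))
  expect_equal(shade_factor(0.4, 0.5), exp(0.2))
  # sign convention switch flips the law
  expect_equal(shade_factor(0.4, 0.5, sign = -1), exp(-0.2))
  expect_error(shade_factor(0.3, 1))
})

test_that("leaf profile CDF has the documented closed-form properties", {
  h <- seq(0.05, 0.95, by = 0.1)
  # uniform case
  expect_equal(leaf_profile_cdf(h, 0.5, 1), h)
  # median at RLH by construction
  for (r in c(0.3, 0.5, 0.7))
    expect_equal(leaf_profile_cdf(r, r, 2.7), 0.5)
  # larger b concentrates area: steeper at the median
  expect_lt(leaf_profile_cdf(0.35, 0.5, 4), leaf_profile_cdf(0.35, 0.5, 1))
  # quantile inverts the cdf
  p <- c(0.1, 0.5, 0.9)
  expect_equal(leaf_profile_cdf(leaf_profile_quantile(p, 0.4, 3), 0.4, 3),
               p, tolerance = 1e-12)
})

test_that("noise-free garden plots obey the generating laws exactly", {
  v <- toy_variety(mu_HM = 0.4)
  g <- gen_garden_plot(v, stages = c(4, 6), nPerStage = 4,
                       shadeLevels = c(0, 0.5), noiseCV = 0, seed = 2)
  un <- g[!g$shaded, ]
  expect_equal(un$height, 20 * un$aboveGroundBiomass^0.3, tolerance = 1e-12)
  sh <- g[g$shaded, ]
  expect_equal(sh$height, 20 * exp(0.4 * 0.5) * sh$aboveGroundBiomass^0.3,
               tolerance = 1e-12)
  expect_equal(g$leafBiomass / g$aboveGroundBiomass,
               pmin(0.8 * shade_factor(0.05, g$shadingIntensity), 1),
               tolerance = 1e-12)
  expect_equal(g$leafArea / g$leafBiomass,
               150 * shade_factor(0.08, g$shadingIntensity),
               tolerance = 1e-12)
  for (p in g$leafProfile) {
    expect_true(all(diff(p$cumulativeLeafAreaFraction) >= -1e-12))
    expect_equal(tail(p$cumulativeLeafAreaFraction, 1), 1)
  }
  expect_true(all(g$shadingIntensity[!g$shaded] == 0))
})

test_that("garden plot generator rejects invalid designs and is reproducible", {
  v <- toy_variety()
  expect_error(gen_garden_plot(v, noiseCV = -0.1), "noiseCV")
  expect_error(gen_garden_plot(v, shadeLevels = c(0, 1)), "shade")
  expect_error(gen_garden_plot(v, shadeLevels = c(0.3, 0.6)), "include 0")
  a <- gen_garden_plot(v, noiseCV = 0.05, seed = 4)
  b <- gen_garden_plot(v, noiseCV = 0.05, seed = 4)
  expect_identical(a, b)
  d <- gen_garden_plot(v, noiseCV = 0.05, seed = 5)
  expect_false(identical(a$height, d$height))
})

test_that("garden plot CSV round-trips including leaf profiles", {
  v <- toy_variety()
  g <- gen_garden_plot(v, stages = c(4, 8), nPerStage = 3, noiseCV = 0.02,
                       seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_garden_csv(g, f)
  g2 <- read_garden_csv(f)
  expect_equal(g2$height, g$height, tolerance = 1e-12)
  expect_equal(g2$leafProfile[[5]]$cumulativeLeafAreaFraction,
               g$leafProfile[[5]]$cumulativeLeafAreaFraction,
               tolerance = 1e-12)
})

test_that("variety JSON round-trips exactly", {
  vs <- pea_reference_varieties()
  f <- withr::local_tempfile(fileext = ".json")
  write_varieties_json(vs, f)
  vs2 <- read_varieties_json(f)
  expect_equal(flatten_variety(vs2$Isard), flatten_variety(vs$Isard))
  expect_equal(vs2$China$seasonality, "winter_Hr")
})

test_that("weather series: calendar, sinusoid, rain and determinism", {
  w <- gen_weather(12, seed = 7)
  expect_equal(nrow(w), 4383)  # 12 years with 3 leap days
  expect_true(all(diff(w$date) == 1))
  expect_true(all(w$PAR >= 0) && all(w$rainfall >= 0))
  # noise-free temperature equals the stated sinusoid exactly
  cl <- default_climate()
  cl$tempSd <- 0; cl$parSd <- 0; cl$rainRate <- 0
  w0 <- gen_weather(1, seed = 1, climate = cl)
  doy <- as.integer(format(w0$date, "%j"))
  expect_equal(w0$meanTemperature, seasonal_temperature(doy, cl),
               tolerance = 1e-12)
  expect_equal(w0$rainfall, rep(0, nrow(w0)))
  expect_identical(gen_weather(2, seed = 9), gen_weather(2, seed = 9))
})

test_that("weed pools have the required sizes and composition", {
  full <- gen_weed_pool("complete", seed = 1)
  expect_length(full, 26)
  harm <- gen_weed_pool("harmful", seed = 1)
  expect_length(harm, 6)
  bee <- gen_weed_pool("bee_food", seed = 1)
  expect_length(bee, 6)
  expect_true(all(vapply(bee, function(w)
    !isTRUE(w$monocot) && w$beeAttractiveness > 0, logical(1))))
  expect_identical(names(gen_weed_pool("bee_food", seed = 3)),
                   names(gen_weed_pool("bee_food", seed = 3)))
  expect_error(gen_weed_pool("nonsense"), "arg")
  for (w in full) {
    expect_silent(validate_variety(w))
    expect_true(w$seedAllocation > 0 && w$seedAllocation <= 1)
  }
})

test_that("initial seed bank is non-negative with dormant fractions in [0,1]", {
  pool <- sim_fixture()$pool
  bank <- new_seed_bank(pool, seedsPerSpecies = 100, fieldArea = 20)
  expect_equal(dim(bank), c(26, 31))
  expect_true(all(bank >= 0))
  df <- attr(bank, "dormantFraction")
  expect_true(all(df >= 0 & df <= 1))
  # surface-biased: top 5 layers hold the majority
  expect_gt(sum(bank[, 1:5]), sum(bank[, 6:31]))
})
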