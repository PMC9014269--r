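test_that("germination fraction follows the stated thermal-time law", {
  expect_equal(germination_fraction(15, 15, 30, 2.3), 0)
  expect_equal(germination_fraction(10, 15, 30, 2.3), 0)
  expect_equal(germination_fraction(30, 15, 30, 2.3), 0.5)
  # closed form at tt = 45 with gb = 2: (1 - 2^-4); surface modifier 0.54
  expect_equal(germination_fraction(45, 15, 30, 2) * 0.54,
               (1 - 2^-4) * 0.54)
  expect_equal(germination_fraction(45, 15, 30, 2) * 0.54, 0.50625)
  # independent evaluation for a non-integer shape
  expect_equal(germination_fraction(45, 15, 30, 2.3),
               1 - exp(-log(2) * 2^2.3), tolerance = 1e-12)
  expect_error(germination_fraction(10, 20, 20, 2), "g50")
})

test_that("pre-emergence kinetics and mortality behave as documented", {
  # elongation: half the maximum at tt = r50, saturating at shootLength
  expect_equal(shoot_elongation(100, 400, 100, 1.4), 200)
  expect_lt(shoot_elongation(1e6, 400, 100, 1.4), 400 + 1e-6)
  # surface seed: only the intercept applies
  expect_equal(seedling_mortality(1, 0.34, m0 = 0.05), 0.05)
  # 20 mm depth with gamma = 0.34 clamps to certain death
  expect_equal(seedling_mortality(20, 0.34, m0 = 0), 1)
  expect_equal(seedling_mortality(20, 0.34, m0 = 0.05), 1)
  expect_equal(seedling_mortality(5, 0.2, m0 = 0), 0.2 * log(5))
})

test_that("temperature response ramps linearly between its bounds", {
  expect_equal(temperature_response(0.2, 0.2, 19.6), 0)
  expect_equal(temperature_response(-5, 0.2, 19.6), 0)
  expect_equal(temperature_response((0.2 + 19.6) / 2, 0.2, 19.6), 0.5)
  expect_equal(temperature_response(25, 0.2, 19.6), 1)
})

test_that("BBCH mapping hits the phenophase boundaries exactly", {
  expect_equal(bbch_stage(0, 1000, 400, 500), 0)
  expect_equal(bbch_stage(500, 1000, 400, 500), 2)
  expect_equal(bbch_stage(1000, 1000, 400, 500), 4)  # flowering onset
  expect_equal(bbch_stage(1400, 1000, 400, 500), 8)
  expect_equal(bbch_stage(1900, 1000, 400, 500), 10)
  expect_equal(bbch_stage(99999, 1000, 400, 500), 10)
})

test_that("tillage mixing conserves seeds and is idempotent at fixed depth", {
  pool <- sim_fixture()$pool
  bank <- new_seed_bank(pool, seedsPerSpecies = 137)
  before <- rowSums(bank)
  mixed <- mix_seed_layers(bank, 17)
  expect_equal(rowSums(mixed), before, tolerance = 1e-9)
  # uniform mixing is idempotent: two passes at 10 cm equal one pass
  once <- mix_seed_layers(bank, 10)
  twice <- mix_seed_layers(once, 10)
  expect_equal(unclass(twice), unclass(once), tolerance = 1e-12,
               ignore_attr = TRUE)
  # layers 0..10 are equalized
  expect_equal(diff(range(once[1, 1:11])), 0, tolerance = 1e-12)
  # zero depth is a no-op
  expect_equal(unclass(mix_seed_layers(bank, 0)), unclass(bank),
               ignore_attr = TRUE)
})

test_that("light partition: isolation, height ordering, and the brute-force
           oracle", {
  cfg <- sim_config(cellSize = 0.5, layerSize = 1, maxLayers = 0)
  single <- data.frame(x = 1, y = 1, height = 60, width = 30,
                       leafArea = 600, rlh = 0.5, brlh = 2)
  lp1 <- light_partition(single, 5, 2, 2, cfg)
  expect_equal(lp1$shading, 0)  # no self-shading
  expect_gt(lp1$absorbedMJ, 0)
  # two identical coaxial plants, one twice as tall
  two <- data.frame(x = c(1, 1), y = c(1, 1), height = c(100, 50),
                    width = c(30, 30), leafArea = c(600, 600),
                    rlh = c(0.5, 0.5), brlh = c(2, 2))
  lp2 <- light_partition(two, 5, 2, 2, cfg)
  expect_equal(lp2$shading[1], 0)
  expect_gt(lp2$shading[2], 0)
  expect_gt(lp2$absorbedMJ[1], lp2$absorbedMJ[2])
  # three-plant toy configuration on a 2 x 2 m field vs the independent
  # R integration
  three <- data.frame(x = c(0.5, 1.2, 1.4), y = c(0.5, 1.5, 0.6),
                      height = c(80, 45, 120), width = c(40, 60, 25),
                      leafArea = c(900, 1200, 500),
                      rlh = c(0.45, 0.6, 0.5), brlh = c(2.5, 1.8, 3))
  lp3 <- light_partition(three, 4.7, 2, 2, cfg)
  orc <- light_oracle(three, 4.7, 2, 2, cfg$cellSize, cfg$layerSize, cfg$k)
  expect_equal(lp3$absorbedMJ, orc$absorbedMJ, tolerance = 1e-8)
  expect_equal(lp3$shading, orc$shading, tolerance = 1e-8)
  # energy conservation: absorbed cannot exceed incident on the field
  expect_lt(sum(lp3$absorbedMJ), 4.7 * 4)
  expect_error(light_partition(single, 5, 0, 2, cfg), "zero-area")
})

test_that("simulations are deterministic and conserve the seed bank", {
  fx <- sim_fixture()
  plan <- build_plan(fx$situations$reference, 2, fx$varieties, seed = 11)
  r1 <- simulate_system(plan[[1]], fx$varieties, fx$pool, fx$weather,
                        fx$bank, weedy = TRUE, seed = 5, nYears = 2)
  r2 <- simulate_system(plan[[1]], fx$varieties, fx$pool, fx$weather,
                        fx$bank, weedy = TRUE, seed = 5, nYears = 2)
  expect_identical(r1$years, r2$years)
  expect_identical(r1$bank, r2$bank)
  # conservation: initial - germinated + returned = final
  expect_equal(unname(r1$audit["initial"] - r1$audit["germinated"] +
                        r1$audit["returned"]), sum(r1$bank),
               tolerance = 1e-6)
  expect_true(all(r1$years$yield_t_ha >= 0))
})

test_that("matched-stream weed-free runs dominate weedy runs", {
  fx <- sim_fixture()
  plan <- build_plan(fx$situations$reference, 3, fx$varieties, seed = 21)
  for (s in plan) {
    pr <- simulate_pair(s, fx$varieties, fx$pool, fx$weather, fx$bank,
                        seed = 13, nYears = 2)
    expect_true(all(pr$weedfree$years$yield_t_ha >=
                      pr$weedy$years$yield_t_ha - 1e-9))
    expect_equal(pr$weedfree$years$year, pr$weedy$years$year)
    expect_equal(sum(pr$weedfree$years$weedBiomass_t_ha), 0)
  }
})

test_that("degenerate climates: zero PAR means zero biomass and yield", {
  fx <- sim_fixture()
  plan <- build_plan(fx$situations$reference, 1, fx$varieties, seed = 2)
  dark <- fx$weather
  dark$PAR <- 0
  r <- simulate_system(plan[[1]], fx$varieties, fx$pool, dark, fx$bank,
                       weedy = TRUE, seed = 3, nYears = 2)
  expect_equal(sum(r$years$yield_t_ha), 0)
  expect_equal(sum(r$years$weedBiomass_t_ha), 0)
})

test_that("empty seed bank and no sowing produce no plants and no yield", {
  fx <- sim_fixture()
  plan <- build_plan(fx$situations$reference, 1, fx$varieties, seed = 2)
  s <- plan[[1]]
  for (cr in names(s$operations))
    s$operations[[cr]] <-
      s$operations[[cr]][s$operations[[cr]]$kind != "sowing", ]
  empty <- fx$bank
  empty[] <- 0
  r <- simulate_system(s, fx$varieties, fx$pool, fx$weather, empty,
                       weedy = TRUE, seed = 3, nYears = 2)
  expect_equal(sum(r$years$yield_t_ha), 0)
  expect_equal(sum(r$years$cropPlants), 0)
  expect_equal(sum(r$years$weedBiomass_t_ha), 0)
  expect_equal(sum(r$years$speciesRichness), 0)
})

test_that("weather gaps are a hard error", {
  fx <- sim_fixture()
  plan <- build_plan(fx$situations$reference, 1, fx$varieties, seed = 2)
  short <- fx$weather[1:200, ]
  expect_error(simulate_system(plan[[1]], fx$varieties, fx$pool, short,
                               fx$bank, weedy = TRUE, seed = 3,
                               nYears = 2), "weather gap")
})

test_that("herbicides, tillage and weed caps act on the weed stand", {
  fx <- sim_fixture()
  plan <- build_plan(fx$situations$reference, 6, fx$varieties, seed = 31)
  # find a system with at least one herbicide pass and compare against the
  # same system with herbicides stripped
  has <- vapply(plan, function(s)
    sum(s$operations$pea$kind == "herbicide") > 0, logical(1))
  s <- plan[which(has)[1]]
  s <- s[[1]]
  noHerb <- s
  noHerb$operations$pea <-
    noHerb$operations$pea[noHerb$operations$pea$kind != "herbicide", ]
  rH <- simulate_system(s, fx$varieties, fx$pool, fx$weather, fx$bank,
                        weedy = TRUE, seed = 7, nYears = 1)
  r0 <- simulate_system(noHerb, fx$varieties, fx$pool, fx$weather,
                        fx$bank, weedy = TRUE, seed = 7, nYears = 1)
  peaH <- rH$years[rH$years$crop == "pea", ]
  pea0 <- r0$years[r0$years$crop == "pea", ]
  if (nrow(peaH) == 1 && nrow(pea0) == 1) {
    expect_lte(peaH$weedBiomass_t_ha, pea0$weedBiomass_t_ha + 1e-9)
  }
  expect_gte(nrow(rH$years), 1)
})

test_that("one default system-year simulates within the speed budget", {
  fx <- sim_fixture()
  plan <- build_plan(fx$situations$reference, 1, fx$varieties, seed = 11)
  t0 <- Sys.time()
  invisible(simulate_system(plan[[1]], fx$varieties, fx$pool, fx$weather,
                            fx$bank, weedy = TRUE, seed = 6, nYears = 3))
  perYear <- as.numeric(Sys.time() - t0, units = "secs") / 3
  expect_lt(perYear, 2)
})

test_that("compiled morphology update matches the R reference", {
  fx <- sim_fixture()
  reg <- cropideo:::.build_registry(c(fx$pool[1:3],
                                      fx$varieties["Kayanne"]))
  set.seed(2)
  n <- 40
  pl <- list(sp = sample(1:4, n, TRUE), isCrop = rep(FALSE, n),
             x = runif(n), y = runif(n), B = runif(n, 0, 20),
             tt = runif(n, 0, 2000), stage = runif(n, 0, 10),
             s = runif(n, 0, 0.9), height = rep(1, n), width = rep(1, n),
             leafArea = rep(0, n), rlh = rep(0.5, n), brlh = rep(2, n))
  rref <- cropideo:::.update_morphology(pl, reg, 1)
  cpp <- cropideo:::.update_morphology_cpp(
    pl$sp, pl$stage, pl$s, pl$B, pl$tt, reg$stages,
    reg$scalars$max_height, reg$scalars$max_width,
    reg$scalars$LA0, reg$scalars$RGR, 1)
  for (f in c("height", "width", "leafArea", "rlh", "brlh"))
    expect_equal(rref[[f]], cpp[[f]], tolerance = 1e-12)
})
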