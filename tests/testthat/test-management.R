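test_that("the nine preset situations match their stated constraints", {
  sits <- situation_presets()
  expect_length(sits, 9)
  ref <- sits$reference
  expect_setequal(ref$crops, c("pea", "winter_wheat", "WOSR"))
  expect_true(ref$tillageAllowed && ref$herbicidesAllowed)
  expect_false(ref$mechanicalWeedingAllowed)
  expect_equal(ref$fertilizerType, "mineral")
  expect_equal(ref$weedPoolKind, "complete")
  org <- sits$organic
  expect_false(org$herbicidesAllowed)
  expect_true(org$mechanicalWeedingAllowed)
  expect_equal(org$fertilizerType, "organic")
  expect_false(sits$no_till$tillageAllowed)
  expect_length(sits$rotation2$crops, 2)
  expect_length(sits$rotation6$crops, 6)
  expect_equal(sits$harmful$weedPoolKind, "harmful")
  expect_equal(sits$harmful_bee$weedPoolKind, "bee_food")
})

test_that("sampled techniques respect windows, envelopes and quantile maps", {
  sits <- situation_presets()
  vs <- pea_reference_varieties()
  row1 <- setNames(rep(0.5, 16), cropideo:::.tech_vars)
  # pea sowing-date quantile 0 maps to 1 October (crop-year offset 61)
  r0 <- row1; r0["sow_q"] <- 0
  o0 <- sample_crop_techniques("pea", sits$reference, r0, vs$Kayanne)
  expect_equal(o0$day[o0$kind == "sowing"], 61)
  # quantile 1 maps to 15 April for a short-cycle spring variety
  r1 <- row1; r1["sow_q"] <- 1
  o1 <- sample_crop_techniques("pea", sits$reference, r1, vs$Kayanne)
  expect_equal(o1$day[o1$kind == "sowing"], 257)
  # a long-cycle winter variety drawn late is clamped earlier so that it
  # can still mature
  slow <- vs$China
  slow$PeaFloweringTT <- 2400
  oC <- sample_crop_techniques("pea", sits$reference, r1, slow)
  expect_lt(oC$day[oC$kind == "sowing"], 257)
  # and a variety that can never mature in the window is a hard error
  never <- vs$China
  never$PeaFloweringTT <- 4000
  expect_error(sample_crop_techniques("pea", sits$reference, r1, never),
               "constraint error")
  # winter wheat can never be sown in spring: the window itself is autumnal
  ow <- sample_crop_techniques("winter_wheat", sits$reference, r1,
                               crop_presets()$winter_wheat)
  sowW <- ow$day[ow$kind == "sowing"]
  expect_true(sowW >= 61 && sowW <= 136)
  # no-till situations sample no tillage operations
  ont <- sample_crop_techniques("pea", sits$no_till, row1, vs$Kayanne)
  expect_equal(sum(ont$kind == "tillage"), 0)
  expect_error(sample_crop_techniques("potato", sits$reference, row1,
                                      vs$Kayanne), "unknown crop")
})

test_that("plans obey situation constraints and their own validator", {
  vs <- pea_reference_varieties()
  sits <- situation_presets()
  plan <- build_plan(sits$reference, 12, vs, seed = 11)
  expect_length(plan, 12)
  for (s in plan) expect_true(validate_cropping_system(s))
  org <- build_plan(sits$organic, 6, vs, seed = 2)
  expect_equal(sum(vapply(org, function(s)
    sum(vapply(s$operations, function(o) sum(o$kind == "herbicide"),
               numeric(1))), numeric(1))), 0)
  expect_gte(sum(vapply(org, function(s)
    sum(vapply(s$operations, function(o)
      sum(o$kind == "mechanical_weeding"), numeric(1))), numeric(1))), 0)
  nt <- build_plan(sits$no_till, 6, vs, seed = 2)
  expect_equal(sum(vapply(nt, function(s)
    sum(vapply(s$operations, function(o) sum(o$kind == "tillage"),
               numeric(1))), numeric(1))), 0)
  for (s in c(org, nt)) expect_true(validate_cropping_system(s))
})

test_that("continuous technique variables are LHS-stratified across systems", {
  vs <- pea_reference_varieties()
  plan <- build_plan(situation_presets()$reference, 20, vs, seed = 11)
  dens <- vapply(plan, function(s)
    s$operations$pea$density[s$operations$pea$kind == "sowing"],
    numeric(1))
  strata <- ceiling((dens - 25) / (115 - 25) * 20 - 1e-9)
  expect_setequal(strata, 1:20)
  inter <- vapply(plan, function(s)
    s$operations$pea$interrow[s$operations$pea$kind == "sowing"],
    numeric(1))
  expect_setequal(ceiling((inter - 4) / (52 - 4) * 20 - 1e-9), 1:20)
})

test_that("plans are deterministic under seed and vary across seeds", {
  vs <- pea_reference_varieties()
  a <- build_plan(situation_presets()$reference, 5, vs, seed = 4)
  b <- build_plan(situation_presets()$reference, 5, vs, seed = 4)
  expect_identical(lapply(a, `[[`, "operations"),
                   lapply(b, `[[`, "operations"))
  d <- build_plan(situation_presets()$reference, 5, vs, seed = 5)
  expect_false(identical(lapply(a, `[[`, "operations"),
                         lapply(d, `[[`, "operations")))
})

test_that("the validator flags violations", {
  vs <- pea_reference_varieties()
  s <- build_plan(situation_presets()$reference, 1, vs, seed = 1)[[1]]
  bad <- s
  bad$rotation <- c("pea", "maize")
  expect_error(validate_cropping_system(bad), "outside")
  bad2 <- s
  bad2$operations$pea$day[bad2$operations$pea$kind == "sowing"] <- 500
  expect_error(validate_cropping_system(bad2))
  bad3 <- s
  i <- which(bad3$operations$pea$kind == "tillage")[1]
  bad3$operations$pea$day[i] <-
    bad3$operations$pea$day[bad3$operations$pea$kind == "sowing"] + 5
  expect_error(validate_cropping_system(bad3), "tillage after")
})

test_that("correlation audit: magnitudes, permutation invariance, NA for
           degenerate plans", {
  vs <- pea_reference_varieties()
  plan <- build_plan(situation_presets()$reference, 40, vs, seed = 11)
  aud <- audit_plan_correlations(plan, vs)
  tech <- aud$report[aud$report$group1 == "technique" &
                       aud$report$group2 == "technique", ]
  expect_lte(tech$medianAbsR, 0.15)
  shuffled <- audit_plan_correlations(plan[sample(length(plan))], vs)
  expect_equal(aud$report$medianAbsR, shuffled$report$medianAbsR,
               tolerance = 1e-12)
  # all-identical systems: correlations undefined, reported NA
  same <- rep(plan[1], 12)
  audSame <- audit_plan_correlations(same, vs)
  expect_true(all(is.na(audSame$report$medianAbsR) |
                    audSame$report$n == 0))
  expect_error(audit_plan_correlations(plan[1:5]), ">= 10")
})

test_that("plan CSV export writes one row per operation", {
  vs <- pea_reference_varieties()
  plan <- build_plan(situation_presets()$reference, 3, vs, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  m <- withr::local_tempfile(fileext = ".json")
  write_plan_csv(plan, f, m)
  tab <- read.csv(f)
  nOps <- sum(vapply(plan, function(s)
    sum(vapply(s$operations, nrow, integer(1))), numeric(1)))
  expect_equal(nrow(tab), nOps)
  expect_true(all(c("systemId", "kind", "day", "crop") %in% names(tab)))
  man <- jsonlite::read_json(m)
  expect_equal(man$nSystems, 3L)
})
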