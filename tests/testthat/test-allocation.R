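# ABODE and PPA estimators, agreement classification, setback conflicts.

oneBlockFixture <- function(pop = 100, gq = 0, hu = 40, size = 1000) {
  censusBlocks(list(unitSquare(0, 0, size)), "B1", pop, gq, hu)
}

test_that("RHUs in a well area are counted per block, boundary inclusive", {
  blocks <- oneBlockFixture()
  rhus <- rhuTable(x = c(500, 510, 490, 900), y = c(500, 500, 500, 900),
                   block_id = "B1")
  area <- makeWellAreas(data.frame(well_id = "w", x = 500, y = 500), 50,
                        blocks)[[1]]
  expect_identical(rhusInArea(area, rhus), c(B1 = 3L))
  # a unit at exactly the radius counts (closed-circle rule)
  rhus2 <- rhuTable(x = c(550), y = c(500), block_id = "B1")
  expect_identical(rhusInArea(area, rhus2), c(B1 = 1L))
  rhus3 <- rhuTable(x = c(550.01), y = c(500), block_id = "B1")
  expect_identical(rhusInArea(area, rhus3), integer(0))
})

test_that("RHU counting matches a brute-force distance oracle on 200 fixtures", {
  set.seed(77)
  blocks <- oneBlockFixture()
  agree <- TRUE
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    rhus <- rhuTable(x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                     block_id = "B1")
    ctr <- runif(2, 100, 900)
    r <- runif(1, 30, 300)
    area <- makeWellAreas(data.frame(well_id = "w", x = ctr[1], y = ctr[2]),
                          r, blocks)[[1]]
    got <- sum(rhusInArea(area, rhus))
    want <- sum(sqrt((rhus$x - ctr[1])^2 + (rhus$y - ctr[2])^2) <= r)
    agree <- agree && got == want
  }
  expect_true(agree)
})

test_that("block cap factor follows min(1, HU/RHU) with degenerate guards", {
  expect_equal(blockCapFactor(5, 10), 0.5)
  expect_equal(blockCapFactor(10, 7), 1)
  expect_equal(blockCapFactor(0, 3), 0)
  expect_equal(blockCapFactor(4, 0), 1)
  expect_error(blockCapFactor(-1, 3), "negative")
})

test_that("ABODE arithmetic: uncapped, multi-block, capped, zero-RHU", {
  b <- censusBlocks(list(unitSquare(0, 0, 1000), unitSquare(1000, 0, 1000)),
                    c("B1", "B2"), c(10, 9), c(0, 0), c(4, 3))
  # pph: B1 = 2.5, B2 = 3.0
  rhus <- rhuTable(x = c(990, 992, 994, 996, 1004, 1006),
                   y = rep(500, 6),
                   block_id = c("B1", "B1", "B1", "B1", "B2", "B2"))
  wells <- data.frame(well_id = "w", x = 1000, y = 500)
  area <- makeWellAreas(wells, 50, b)[[1]]
  unc <- abodePopulation(area, b, rhus, capped = FALSE)
  expect_equal(unc$population, 4 * 2.5 + 2 * 3.0)  # 16
  expect_equal(unc$rhu_count, 6L)

  # one block, pph 2.5, 4 RHUs -> 10
  area1 <- makeWellAreas(data.frame(well_id = "w", x = 993, y = 500), 5,
                         b)[[1]]
  expect_equal(abodePopulation(area1, b, rhus, capped = FALSE)$population,
               10)

  # capping: block pph 2, HU 5, 10 block-wide RHUs, 4 in area -> 4*0.5*2
  b2 <- censusBlocks(list(unitSquare(0, 0, 1000)), "B1", 10, 0, 5)
  rhus2 <- rhuTable(x = seq(100, 1000 - 100, length.out = 10), y = 500,
                    block_id = "B1")
  area2 <- makeWellAreas(data.frame(well_id = "w", x = 250, y = 500), 165,
                         b2)[[1]]
  expect_equal(sum(rhusInArea(area2, rhus2)), 4L)
  capped <- abodePopulation(area2, b2, rhus2, capped = TRUE)
  expect_equal(capped$population, 4 * 0.5 * 2)  # 4, vs uncapped 8
  expect_equal(abodePopulation(area2, b2, rhus2, capped = FALSE)$population,
               8)
  # hard cap mode truncates the per-area count instead
  hard <- abodePopulation(area2, b2, rhus2, capped = TRUE, capMode = "hard")
  expect_equal(hard$population, 4 * 2)  # min(4, 5) * pph, cap inactive

  # zero RHUs in range -> exactly zero population
  areaFar <- makeWellAreas(data.frame(well_id = "w", x = 500, y = 5), 2,
                           b2)[[1]]
  z <- abodePopulation(areaFar, b2, rhus2, capped = TRUE)
  expect_identical(z$rhu_count, 0L)
  expect_identical(z$population, 0)
})

test_that("group-quarters warning is raised for intersected blocks with GQ", {
  b <- oneBlockFixture(pop = 100, gq = 20, hu = 40)
  rhus <- rhuTable(x = 500, y = 500, block_id = "B1")
  area <- makeWellAreas(data.frame(well_id = "w", x = 500, y = 500), 50,
                        b)[[1]]
  expect_true(abodePopulation(area, b, rhus)$gq_warning)
  b0 <- oneBlockFixture(gq = 0)
  expect_false(abodePopulation(area, b0, rhus)$gq_warning)
})

test_that("PPA: closed-form single block, symmetry, outside-all-blocks", {
  b <- oneBlockFixture(pop = 100, size = 1000)  # density 1e-4
  wells <- data.frame(well_id = "w", x = 500, y = 500)
  area <- makeWellAreas(wells, 200, b)[[1]]
  got <- ppaPopulation(area, b)$population
  expect_equal(got, 1e-4 * pi * 200^2, tolerance = 0.005)  # ~12.566

  # half of the block by symmetry
  leftHalf <- planarPolygon(rbind(c(0, 0), c(500, 0), c(500, 1000),
                                  c(0, 1000), c(0, 0)))
  expect_equal(ppaPopulation(leftHalf, b)$population, 50, tolerance = 1e-9)

  far <- makeWellAreas(data.frame(well_id = "w", x = 9000, y = 9000), 200,
                       b)[[1]]
  expect_equal(ppaPopulation(far, b)$population, 0)
})

test_that("PPA conserves the block population over its full geometry", {
  cfg <- scenarioConfig(nx = 3, ny = 3, blockSize = 400, meanHuPerBlock = 20,
                        nWells = 1, seed = 5)
  blocks <- generateRegion(cfg)$blocks
  for (k in seq_len(length(blocks))) {
    got <- ppaPopulation(geometries(blocks)[[k]], blocks)$population
    want <- totalPopulation(blocks)[k]
    if (want > 0) expect_lt(abs(got - want) / want, 1e-6)
    else expect_lt(abs(got - want), 1e-6)
  }
})

test_that("PPA agrees with a Monte-Carlo point-sampling oracle", {
  set.seed(23)
  cfg <- scenarioConfig(nx = 2, ny = 2, blockSize = 500, meanHuPerBlock = 30,
                        nWells = 1, seed = 6)
  blocks <- generateRegion(cfg)$blocks
  ctr <- c(480, 510); r <- 220
  area <- makeWellAreas(data.frame(well_id = "w", x = ctr[1], y = ctr[2]),
                        r, blocks, nSegments = 512)[[1]]
  got <- ppaPopulation(area, blocks)$population
  # oracle: uniform points per block, weighted by block density, counted
  # when inside the circle (pure distance test, no polygon code)
  dens <- populationDensity(blocks)
  want <- 0
  for (k in seq_len(length(blocks))) {
    ring <- geometries(blocks)[[k]]@rings[[1]]
    xr <- range(ring[, 1]); yr <- range(ring[, 2])
    x <- runif(1e6, xr[1], xr[2]); y <- runif(1e6, yr[1], yr[2])
    inBlk <- sp::point.in.polygon(x, y, ring[, 1], ring[, 2]) == 1
    inCirc <- (x - ctr[1])^2 + (y - ctr[2])^2 <= r^2
    cellArea <- (xr[2] - xr[1]) * (yr[2] - yr[1])
    want <- want + mean(inBlk & inCirc) * cellArea * dens[k]
  }
  expect_lt(abs(got - want) / want, 0.01)
})

test_that("both estimators are non-decreasing in radius", {
  cfg <- scenarioConfig(nx = 3, ny = 3, blockSize = 400, meanHuPerBlock = 25,
                        nWells = 1, seed = 8)
  region <- generateRegion(cfg)
  rhus <- buildRhus(region$candidates, region$landUse, region$blocks)
  wells <- data.frame(well_id = "w", x = 600, y = 600)
  radii <- c(50, 100, 200, 400, 800)
  res <- lapply(radii, function(r)
    allocateWells(wells, r, region$blocks, rhus))
  abode <- vapply(res, function(d) d$abode_uncapped, numeric(1))
  ppa <- vapply(res, function(d) d$ppa, numeric(1))
  expect_true(all(diff(abode) >= 0))
  expect_true(all(diff(ppa) >= -1e-9))
})

test_that("capped ABODE never exceeds uncapped, and caps bound the universe", {
  cfg <- scenarioConfig(nx = 4, ny = 4, nWells = 25, seed = 12,
                        nonresidentialRate = 0.3,
                        commercialCellFraction = 0.1)
  region <- generateRegion(cfg)
  # skip censoring: contaminants inflate block RHU counts above census HU
  rhus <- assignBlocks(region$candidates, region$blocks)
  rhus <- rhus[!is.na(rhus$block_id), ]
  pw <- allocateWells(region$wells, 200, region$blocks, rhus)
  expect_true(all(pw$abode_capped <= pw$abode_uncapped + 1e-9))
  expect_true(any(pw$abode_capped < pw$abode_uncapped))
  # capped universe total over the whole region <= household population
  huge <- max(4 * cfg$nx * cfg$blockSize, 4 * cfg$ny * cfg$blockSize)
  ctr <- data.frame(well_id = "all", x = cfg$nx * cfg$blockSize / 2,
                    y = cfg$ny * cfg$blockSize / 2)
  uni <- universeTotals(ctr, huge, region$blocks, rhus)
  hh <- sum(totalPopulation(region$blocks) -
              groupQuartersPopulation(region$blocks))
  expect_lte(uni$abode_capped, hh + 1e-6)
})

test_that("zero-RHU areas always get zero ABODE population", {
  cfg <- scenarioConfig(nx = 4, ny = 4, nWells = 40, seed = 14,
                        meanHuPerBlock = 6)
  region <- generateRegion(cfg)
  rhus <- buildRhus(region$candidates, region$landUse, region$blocks)
  pw <- allocateWells(region$wells, 100, region$blocks, rhus)
  expect_true(all(pw$abode_capped[pw$rhu_count == 0] == 0))
  expect_true(all(pw$abode_uncapped[pw$rhu_count == 0] == 0))
})

test_that("universe totals avoid double counting across overlapping wells", {
  blocks <- oneBlockFixture(pop = 100, hu = 40)
  rhus <- rhuTable(x = c(450, 550), y = c(500, 500), block_id = "B1")
  pph <- 100 / 40
  # coincident wells count the shared RHUs once
  wells2 <- data.frame(well_id = c("a", "b"), x = c(500, 500),
                       y = c(500, 500))
  uni <- universeTotals(wells2, 100, blocks, rhus)
  expect_equal(uni$rhu_count, 2L)
  expect_equal(uni$abode_uncapped, 2 * pph)
  one <- universeTotals(wells2[1, ], 100, blocks, rhus)
  expect_equal(uni$ppa, one$ppa, tolerance = 1e-9)
  # overlapping wells sharing one RHU still count it once
  rhus3 <- rhuTable(x = c(450, 500, 550), y = rep(500, 3), block_id = "B1")
  wells3 <- data.frame(well_id = c("a", "b"), x = c(460, 540),
                       y = c(500, 500))
  uni3 <- universeTotals(wells3, 60, blocks, rhus3)
  expect_equal(uni3$rhu_count, 3L)  # the shared unit at 500 counted once
  per3 <- allocateWells(wells3, 60, blocks, rhus3)
  expect_equal(sum(per3$rhu_count), 4L)  # per-well rows may overlap
  # disjoint wells: universe equals the sum of the parts
  wells4 <- data.frame(well_id = c("a", "b"), x = c(200, 800),
                       y = c(500, 500))
  uni4 <- universeTotals(wells4, 100, blocks, rhus)
  per <- allocateWells(wells4, 100, blocks, rhus)
  expect_equal(uni4$ppa, sum(per$ppa), tolerance = 1e-8)
  expect_equal(uni4$abode_uncapped, sum(per$abode_uncapped))
})

test_that("agreement classification covers the taxonomy", {
  expect_identical(classifyAgreement(0, 0), "both_zero")
  expect_identical(classifyAgreement(0, 0.4), "fp_low")
  expect_identical(classifyAgreement(0, 1), "fp_low")   # boundary at one
  expect_identical(classifyAgreement(0, 1.2), "fp_high")
  expect_identical(classifyAgreement(5, 3), "both_positive")
  expect_identical(classifyAgreement(2, 0), "other")
  expect_error(classifyAgreement(-1, 0), "negative")
})

test_that("setback conflicts are distance-based and respect missing rules", {
  blocks <- oneBlockFixture()
  rules <- data.frame(state = c("PA", "OH"), setback_ft = c(200, 100))
  wells <- data.frame(well_id = c("w1", "w2"), state = c("PA", "CA"),
                      x = c(500, 700), y = c(500, 500))
  rhus <- rhuTable(x = c(560, 561), y = c(500, 500), block_id = "B1")
  # 200 ft = 60.96 m: the unit at 60 m conflicts, the one at 61 m does not
  expect_warning(res <- setbackConflicts(wells, rules, blocks, rhus),
                 "CA")
  expect_equal(nrow(res), 1L)
  expect_equal(res$setback_m, 60.96)
  expect_equal(res$n_conflict, 1L)
})

test_that("setback conflict counts match a brute-force distance filter", {
  set.seed(31)
  blocks <- oneBlockFixture()
  rules <- data.frame(state = "MI", setback_ft = 300)
  ok <- TRUE
  for (rep in 1:50) {
    n <- sample(3:30, 1)
    rhus <- rhuTable(x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                     block_id = "B1")
    wells <- data.frame(well_id = "w", state = "MI",
                        x = runif(1, 0, 1000), y = runif(1, 0, 1000))
    res <- setbackConflicts(wells, rules, blocks, rhus)
    want <- sum(sqrt((rhus$x - wells$x)^2 + (rhus$y - wells$y)^2) <=
                  300 * 0.3048)
    ok <- ok && res$n_conflict == want
  }
  expect_true(ok)
})
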