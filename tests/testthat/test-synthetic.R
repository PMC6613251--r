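# Synthetic region generator: determinism, construction guarantees, truth.

test_that("generation is deterministic given the seed", {
  cfg <- scenarioConfig(nx = 3, ny = 3, nWells = 10, seed = 42)
  a <- generateRegion(cfg)
  b <- generateRegion(cfg)
  expect_identical(a$candidates, b$candidates)
  expect_identical(a$wells, b$wells)
  expect_identical(a$truth, b$truth)
  expect_identical(a$blocks@data, b$blocks@data)
  expect_identical(a$landUse@classes, b$landUse@classes)
  c <- generateRegion(scenarioConfig(nx = 3, ny = 3, nWells = 10,
                                     seed = 43))
  expect_false(identical(a$candidates, c$candidates))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- runif(1)
  set.seed(1234)
  invisible(generateRegion(scenarioConfig(nx = 2, ny = 2, nWells = 3,
                                          seed = 9)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("with no contaminants and no multi-unit points, candidates equal census HUs", {
  cfg <- scenarioConfig(nx = 3, ny = 3, nonresidentialRate = 0,
                        multiunitRate = 0, nWells = 5, seed = 7)
  region <- generateRegion(cfg)
  expect_equal(nrow(region$candidates), sum(housingUnits(region$blocks)))
  # per block too
  rhus <- assignBlocks(region$candidates, region$blocks)
  counts <- table(factor(rhus$block_id, levels = blockIds(region$blocks)))
  expect_equal(as.vector(counts), housingUnits(region$blocks))
})

test_that("household truth totals reconcile with block populations", {
  cfg <- scenarioConfig(nx = 3, ny = 3, gqFraction = 0, nWells = 5,
                        seed = 11)
  region <- generateRegion(cfg)
  expect_equal(sum(region$truth$persons),
               sum(totalPopulation(region$blocks)))
  # with group quarters, truth covers exactly the household population
  cfg2 <- scenarioConfig(nx = 3, ny = 3, gqFraction = 0.5, nWells = 5,
                         seed = 11)
  region2 <- generateRegion(cfg2)
  expect_gt(sum(groupQuartersPopulation(region2$blocks)), 0)
  expect_equal(sum(region2$truth$persons),
               sum(totalPopulation(region2$blocks)) -
                 sum(groupQuartersPopulation(region2$blocks)))
})

test_that("boundary-clustered households sit within the roadway bandwidth", {
  cfg <- scenarioConfig(nx = 3, ny = 3, placement = "boundary_clustered",
                        boundaryBandwidth = 30, multiunitRate = 0,
                        nonresidentialRate = 0, nWells = 3, seed = 15)
  region <- generateRegion(cfg)
  rhus <- assignBlocks(region$candidates, region$blocks)
  ids <- blockIds(region$blocks)
  maxDist <- 0
  for (k in seq_along(ids)) {
    sel <- which(rhus$block_id == ids[k])
    if (!length(sel)) next
    ring <- geometries(region$blocks)[[k]]@rings[[1]]
    d <- abode:::.distToRing(cbind(rhus$x[sel], rhus$y[sel]), ring)
    maxDist <- max(maxDist, max(d))
  }
  expect_lte(maxDist, 30 + 1e-9)
})

test_that("contaminant points are censored by land use, genuine HUs are not", {
  cfg <- scenarioConfig(nx = 3, ny = 3, nonresidentialRate = 0.2,
                        commercialCellFraction = 0.1, nWells = 3, seed = 19)
  region <- generateRegion(cfg)
  kept <- censorNonresidential(region$candidates, region$landUse)
  nHu <- sum(housingUnits(region$blocks))
  nCon <- nrow(region$candidates) - nHu
  expect_gt(nCon, 0)
  # every contaminant removed (they carry 0 truth persons), every HU kept
  keptTruth <- region$truth[match(kept$candidate_id,
                                  region$truth$candidate_id), ]
  expect_equal(nrow(kept), nHu)
  expect_true(all(keptTruth$persons >= 1))
})

test_that("truthPopulation is exact against a brute-force filter", {
  cfg <- scenarioConfig(nx = 3, ny = 3, nWells = 3, seed = 23)
  region <- generateRegion(cfg)
  s <- cfg$blockSize
  whole <- planarPolygon(rbind(c(-1, -1), c(3 * s + 1, -1),
                               c(3 * s + 1, 3 * s + 1), c(-1, 3 * s + 1),
                               c(-1, -1)))
  expect_equal(truthPopulation(region$truth, whole),
               sum(region$truth$persons))
  nowhere <- planarPolygon(rbind(c(-100, -100), c(-90, -100), c(-90, -90),
                                 c(-100, -90), c(-100, -100)))
  expect_equal(truthPopulation(region$truth, nowhere), 0)
  set.seed(5)
  for (rep in 1:20) {
    ctr <- runif(2, 0, 3 * s); r <- runif(1, 50, 500)
    got <- truthPopulation(region$truth, list(center = ctr, radius = r))
    want <- sum(region$truth$persons[
      sqrt((region$truth$x - ctr[1])^2 +
             (region$truth$y - ctr[2])^2) <= r])
    expect_identical(got, want)
  }
})

test_that("invalid configurations are rejected with the field name", {
  expect_error(scenarioConfig(nx = 0), "nx")
  expect_error(scenarioConfig(multiunitRate = 1.5), "multiunitRate")
  expect_error(scenarioConfig(boundaryBandwidth = -1), "boundaryBandwidth")
})

test_that("uniform placement with constant household size recovers truth exactly", {
  cfg <- scenarioConfig(nx = 4, ny = 4, placement = "uniform",
                        nonresidentialRate = 0, multiunitRate = 0,
                        householdSizeMean = 3, householdSizeSd = 0,
                        gqFraction = 0, nWells = 30, seed = 27)
  region <- generateRegion(cfg)
  rhus <- buildRhus(region$candidates, region$landUse, region$blocks)
  pw <- allocateWells(region$wells, 200, region$blocks, rhus)
  for (i in seq_len(nrow(pw))) {
    w <- region$wells[i, ]
    truth <- truthPopulation(region$truth,
                             list(center = c(w$x, w$y), radius = 200))
    expect_identical(pw$abode_uncapped[i], truth)
    expect_identical(pw$abode_uncapped[i], 3 * pw$rhu_count[i])
  }
})
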