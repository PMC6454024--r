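test_that("simulation config is validated", {
  expect_error(simulationConfig(nGenes = 0), "nGenes")
  expect_error(simulationConfig(nbDispersion = 0), "nbDispersion")
  expect_error(simulationConfig(deFraction = 1.5), "deFraction")
  expect_error(simulationConfig(seedTargetDegree = 20), "seedTargetDegree")
  expect_error(simulationConfig(pathwaySizeRange = c(30, 10)),
               "pathwaySizeRange")
})

test_that("expression simulation plants exactly the configured DE set", {
  ex0 <- simulateExpression(simulationConfig(nGenes = 100, deFraction = 0,
                                             rngSeed = 5))
  expect_true(all(ex0$truth@deLabelsA == "none"))
  expect_true(all(ex0$truth@deLabelsB == "none"))

  ex <- simulateExpression(simulationConfig(nGenes = 1000,
                                            deFraction = 0.05, rngSeed = 5))
  expect_equal(sum(ex$truth@deLabelsA != "none"), 50)
  expect_equal(sum(ex$truth@deLabelsB != "none"), 50)

  # determinism: same seed, same bytes
  exA <- simulateExpression(simulationConfig(nGenes = 200, rngSeed = 7))
  exB <- simulateExpression(simulationConfig(nGenes = 200, rngSeed = 7))
  expect_identical(counts(exA$countsA), counts(exB$countsA))
  expect_identical(counts(exA$countsB), counts(exB$countsB))
  expect_identical(exA$truth, exB$truth)
})

test_that("count marginals match the negative-binomial closed form", {
  # 100 samples per condition gives 200 draws of each non-DE gene at its
  # baseline mean; empirical mean must sit within 3 standard errors of the
  # configured mean, with NB variance mu + phi mu^2
  cfg <- simulationConfig(nGenes = 50, nSamplesPerCondition = 100,
                          deFraction = 0, nbDispersion = 0.05, rngSeed = 19)
  ex <- simulateExpression(cfg)
  m <- counts(ex$countsA)
  mu <- ex$baselineA
  se <- sqrt((mu + 0.05 * mu^2) / ncol(m))
  inBand <- abs(rowMeans(m) - mu) <= 3 * se
  # individually each gene fails with p ~ 0.003; allow one excursion in 50
  expect_gte(sum(inBand), 49)
})

test_that("pathway simulation plants seed hubs and enriched neighborhoods", {
  cfg <- tinyConfig(11, seedGenes = c("gA0003", "gA0007"))
  ex <- simulateExpression(cfg)
  pc <- simulatePathwayCollection(cfg, geneUniverse(cfg, "A"), ex$truth)

  # brute-force degree count straight from the edge lists
  for (s in cfg@seedGenes) {
    partners <- unique(unlist(lapply(pathwayEdges(pc$collection),
      function(e) c(e[e[, 1] == s, 2], e[e[, 2] == s, 1]))))
    expect_gte(length(partners), cfg@seedTargetDegree)
  }

  # neighborhood bookkeeping
  expect_false(any(cfg@seedGenes %in% pc$truth@plantedNeighborhood))
  expect_gt(length(pc$truth@plantedNeighborhood), 0)

  # enrich prob 1 forces every neighborhood node DE
  cfg1 <- tinyConfig(11, seedGenes = c("gA0003", "gA0007"),
                     neighborhoodEnrichProb = 1)
  pc1 <- simulatePathwayCollection(cfg1, geneUniverse(cfg1, "A"), ex$truth)
  expect_true(all(pc1$truth@deLabelsA[pc1$truth@plantedNeighborhood] !=
                  "none"))

  # empty collection when no pathways requested
  cfg0 <- simulationConfig(nGenes = 50, nPathways = 0, rngSeed = 2)
  pc0 <- simulatePathwayCollection(cfg0, geneUniverse(cfg0, "A"), ex$truth)
  expect_equal(length(pc0$collection), 0)

  # unattainable hub degree errors out
  cfgBad <- simulationConfig(nGenes = 30, nPathways = 2,
                             pathwaySizeRange = c(3, 4),
                             seedGenes = "gA0001",
                             seedTargetDegree = 25, rngSeed = 3)
  expect_error(simulatePathwayCollection(cfgBad, geneUniverse(cfgBad, "A"),
                                         simulateExpression(cfgBad)$truth),
               "unattainable")
})

test_that("hit tables recover the truth and exercise the score filter", {
  cfg <- simulationConfig(nGenes = 80, decoyHitFraction = 0, rngSeed = 13)
  ex <- simulateExpression(cfg)
  hits <- simulateHitTable(ex$truth, cfg)
  map <- bestReciprocalHits(filterHits(hits$ab), filterHits(hits$ba))
  got <- homologPairs(map)[, c("geneA", "geneB")]
  want <- ex$truth@homologPairs[order(ex$truth@homologPairs$geneA), ]
  rownames(want) <- NULL
  expect_equal(got, want)

  # decoys include a bit-score right below the filter boundary
  cfgD <- simulationConfig(nGenes = 80, decoyHitFraction = 0.3, rngSeed = 13)
  hitsD <- simulateHitTable(ex$truth, cfgD)
  expect_true(99 %in% c(hitsD$ab$bitscore, hitsD$ba$bitscore))

  # determinism
  hits2 <- simulateHitTable(ex$truth, cfgD)
  expect_identical(hitsD, hits2)
})

test_that("datasets round-trip losslessly through the text formats", {
  cfg <- tinyConfig(4, seedGenes = c("gA0001", "gA0002"))
  ds <- simulateDataset(cfg)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  back <- readDataset(dir)

  expect_identical(counts(back$countsA), counts(ds$countsA))
  expect_identical(conditions(back$countsB), conditions(ds$countsB))
  expect_identical(members(back$pathwaysA), members(ds$pathwaysA))
  expect_identical(pathwayEdges(back$pathwaysA), pathwayEdges(ds$pathwaysA))
  expect_identical(members(back$pathwaysB), members(ds$pathwaysB))
  expect_equal(back$hitsAB, ds$hitsAB, ignore_attr = TRUE)
  expect_identical(back$truth, ds$truth)
  expect_equal(back$config, ds$config)

  # empty collection writes valid zero-line GMT/SIF
  empty <- PathwayCollection(setNames(list(), character(0)))
  writePathwayCollection(empty, file.path(dir, "e.gmt"),
                         file.path(dir, "e.sif"))
  expect_length(readLines(file.path(dir, "e.gmt")), 0)
  reread <- readPathwayCollection(file.path(dir, "e.gmt"),
                                  file.path(dir, "e.sif"))
  expect_equal(length(reread), 0)

  # ids with tabs are rejected
  badM <- matrix(1:2, 1, 2, dimnames = list("bad\tid", c("c", "t")))
  bad <- CountMatrix(badM, c("control", "treated"))
  expect_error(writeCountMatrix(bad, file.path(dir, "bad")), "tab")
})

test_that("expression-derived DE calls agree with the planted truth", {
  # after neighborhood planting, simulateDataset re-syncs treated counts so
  # the pipeline's calls recover the updated labels
  cfg <- simulationConfig(nGenes = 200, nPathways = 12,
                          pathwaySizeRange = c(6, 12), edgeDensity = 0.15,
                          seedGenes = c("gA0001", "gA0002"),
                          deLfcMagnitude = 2, nbDispersion = 0.02,
                          nbMeanLogMu = 6.5, rngSeed = 29)
  ds <- simulateDataset(cfg)
  tab <- expressionTable(ds$countsA)
  truth <- ds$truth@deLabelsA[tab$gene_id]
  called <- tab$de_status != "none"
  expect_gte(sum(called & truth != "none") / sum(truth != "none"), 0.9)
  expect_lte(sum(called & truth == "none") / sum(truth == "none"), 0.1)
})
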