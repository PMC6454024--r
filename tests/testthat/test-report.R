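test_that("hub rows partition by where the DE call fires", {
  tbl <- publishedHubTable()
  cls <- classifyHubRows(tbl)
  actg1 <- cls[cls$gene == "ACTG1", ]
  expect_equal(actg1$partition, "both")
  expect_equal(actg1$agreement, "opposite")
  expect_equal(actg1$degree, 30)
  # a gene under threshold in both species lands in neither
  expect_equal(cls$partition[cls$gene == "AQR"], "a_specific")
})

test_that("hub report joins networks and expression through the map", {
  # species A: star with 25 leaves around hubA; species B: homologous ids
  leavesA <- sprintf("a%02d", 1:25)
  netA <- annotateTopology(mergeNetwork(PathwayCollection(
    list(p = c("hubA", leavesA)), list(p = cbind("hubA", leavesA)))))
  leavesB <- sprintf("b%02d", 1:25)
  netB <- annotateTopology(mergeNetwork(PathwayCollection(
    list(p = c("hubB", leavesB)), list(p = cbind("hubB", leavesB)))))
  map <- methods::new("HomologyMap", pairs = data.frame(
    geneA = c("hubA", leavesA), geneB = c("hubB", leavesB),
    scoreAB = 200, scoreBA = 200))
  tabA <- data.frame(gene_id = c("hubA", leavesA),
                     log2fc = c(1.42, rep(0, 25)),
                     de_status = c("up", rep("none", 25)))
  tabB <- data.frame(gene_id = c("hubB", leavesB),
                     log2fc = c(-1.96, rep(0, 25)),
                     de_status = c("down", rep("none", 25)))
  rep1 <- hubReport(netA, netB, tabA, tabB, map)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$gene, "hubA")
  expect_equal(rep1$partition, "both")
  expect_equal(rep1$log2fc_a, 1.42)
  expect_equal(rep1$log2fc_b, -1.96)
  expect_equal(rep1$degree, 25)

  # no DE hubs: empty report, header only
  tabA0 <- transform(tabA, log2fc = 0, de_status = "none")
  tabB0 <- transform(tabB, log2fc = 0, de_status = "none")
  rep0 <- hubReport(netA, netB, tabA0, tabB0, map)
  expect_equal(nrow(rep0), 0)
  expect_named(rep0, c("gene", "log2fc_a", "log2fc_b", "degree",
                       "neighborhood_connectivity", "partition"))
})

test_that("term profiles tally annotations per gene list", {
  ann <- data.frame(gene_id = c("g1", "g1", "g1", "g2", "g3"),
                    term = c("t1", "t2", "t3", "t1", "t2"))
  p0 <- buildTermProfile(ann, character(0))
  expect_true(all(p0$counts == 0))

  p1 <- buildTermProfile(ann, "g1")
  expect_equal(sum(p1$counts == 1), 3)

  # 20-gene fixture against a brute-force tally
  set.seed(37)
  ann20 <- data.frame(gene_id = sample(sprintf("g%02d", 1:20), 60, TRUE),
                      term = sample(paste0("t", 1:8), 60, TRUE))
  ann20 <- unique(ann20)
  lst <- sprintf("g%02d", 1:12)
  prof <- buildTermProfile(ann20, lst)
  for (tm in names(prof$counts)) {
    expect_equal(prof$counts[[tm]],
                 length(unique(ann20$gene_id[ann20$term == tm &
                                             ann20$gene_id %in% lst])))
  }
  expect_true(all(prof$counts <= prof$listSize))
})

test_that("profile contrast: exact per-term tests and global homogeneity", {
  ann <- data.frame(gene_id = paste0("g", 1:6),
                    term = rep(c("t1", "t2"), 3))
  pA <- buildTermProfile(ann, paste0("g", 1:6))
  same <- compareProfiles(pA, pA)
  expect_true(all(same$table$odds_ratio == 1))
  expect_equal(same$globalP, 1)

  # single term, table [[10,0],[0,10]]: p from hypergeometric enumeration
  pX <- structure(list(counts = c(t1 = 10L), listSize = 10L,
                       unannotated = 0L), class = "TermProfile")
  pY <- structure(list(counts = c(t1 = 0L), listSize = 10L,
                       unannotated = 0L), class = "TermProfile")
  res <- compareProfiles(pX, pY)
  # enumeration oracle: two-sided Fisher sums P(tables as or less likely)
  probs <- dhyper(0:10, 10, 10, 10)
  pOracle <- sum(probs[probs <= dhyper(10, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(res$table$p, pOracle)

  # a term present only in A leans positive (A-leaning sign convention)
  pA2 <- structure(list(counts = c(tOnly = 5L, shared = 5L), listSize = 10L,
                        unannotated = 0L), class = "TermProfile")
  pB2 <- structure(list(counts = c(tOnly = 0L, shared = 5L), listSize = 10L,
                        unannotated = 0L), class = "TermProfile")
  res2 <- compareProfiles(pA2, pB2)
  expect_gt(res2$table$log_ratio[res2$table$term == "tOnly"], 0)

  # BH q-values are monotone in p and bounded
  set.seed(41)
  cA <- setNames(rpois(12, 6), paste0("t", 1:12))
  cB <- setNames(rpois(12, 6), paste0("t", 1:12))
  pBig <- structure(list(counts = cA, listSize = 40L, unannotated = 0L),
                    class = "TermProfile")
  qBig <- structure(list(counts = cB, listSize = 40L, unannotated = 0L),
                    class = "TermProfile")
  res3 <- compareProfiles(pBig, qBig)
  o <- order(res3$table$p)
  expect_true(all(diff(res3$table$q[o]) >= -1e-12))
  expect_true(all(res3$table$q >= 0 & res3$table$q <= 1))

  # global p invariant under term reordering
  perm <- sample(length(cA))
  pPerm <- structure(list(counts = cA[perm], listSize = 40L,
                          unannotated = 0L), class = "TermProfile")
  qPerm <- structure(list(counts = cB[perm], listSize = 40L,
                          unannotated = 0L), class = "TermProfile")
  expect_equal(compareProfiles(pPerm, qPerm)$globalP, res3$globalP)

  expect_error(compareProfiles(pY, pY), "all zero")
})

test_that("the pipeline is a pure function of inputs and seed", {
  cfg <- tinyConfig(6, seedGenes = c("gA0001", "gA0002"))
  ds <- simulateDataset(cfg)
  dir <- withr::local_tempdir()
  writeDataset(ds, file.path(dir, "data"))

  run <- function(out) {
    suppressMessages(runPipeline(pipelineConfig(
      file.path(dir, "data"), file.path(dir, out),
      seeds = c("gA0001", "gA0002"), nPerm = 200, rngSeed = 17)))
  }
  run("out1")
  run("out2")
  f1 <- sort(list.files(file.path(dir, "out1")))
  f2 <- sort(list.files(file.path(dir, "out2")))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(dir, "out1", f)),
                     readLines(file.path(dir, "out2", f)),
                     label = paste("file", f))
  }

  # missing inputs abort with the offending path
  expect_error(runPipeline(pipelineConfig(file.path(dir, "nowhere"),
                                          file.path(dir, "out3"))),
               "counts_a.tsv")
})

test_that("planted seeds reach significance in the pipeline report", {
  cfg <- simulationConfig(nGenes = 250, nPathways = 15,
                          pathwaySizeRange = c(8, 16), edgeDensity = 0.15,
                          seedGenes = c("gA0005", "gA0009"),
                          neighborhoodEnrichProb = 0.9,
                          deLfcMagnitude = 2, nbDispersion = 0.02,
                          nbMeanLogMu = 6.5, rngSeed = 43)
  ds <- simulateDataset(cfg)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  res <- suppressMessages(runPipeline(pipelineConfig(
    dir, file.path(dir, "out"), seeds = cfg@seedGenes, rngSeed = 3)))
  expect_gt(res$nbTest@z, 0)
  expect_lt(res$nbTest@pNormal, 0.05)
})
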