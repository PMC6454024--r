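test_that("pathway selection keeps any pathway touching a DE gene", {
  pc <- PathwayCollection(list(p1 = c("a", "b"), p2 = c("c", "d"),
                               p3 = c("d", "e")))
  sel <- selectPathways(pc, c("d"))
  expect_setequal(pathwayNames(sel), c("p2", "p3"))
  expect_warning(selectPathways(pc, character(0)), "empty")

  # 20-pathway fixture against brute-force intersection
  set.seed(5)
  membs <- setNames(lapply(1:20, function(i) sample(letters, 5)),
                    paste0("pw", 1:20))
  pc20 <- PathwayCollection(membs)
  de <- sample(letters, 6)
  expected <- names(membs)[vapply(membs, function(m)
    length(intersect(m, de)) > 0, logical(1))]
  expect_equal(pathwayNames(selectPathways(pc20, de)), expected)
})

test_that("merging deduplicates edges and separates singletons", {
  # two pathways sharing an edge: counted once
  pc <- PathwayCollection(
    list(p1 = c("a", "b", "c"), p2 = c("a", "b", "z")),
    list(p1 = rbind(c("a", "b"), c("b", "c")), p2 = rbind(c("b", "a"))))
  net <- mergeNetwork(pc)
  expect_equal(igraph::ecount(net@graph), 2)
  expect_equal(singletons(net), "z")
  expect_setequal(nodeNames(net), c("a", "b", "c"))

  # three overlapping pathways against a brute-force union
  set.seed(8)
  mk <- function() {
    memb <- sample(letters[1:12], 6)
    pairs <- t(combn(memb, 2))
    list(m = memb, e = pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE])
  }
  ps <- list(mk(), mk(), mk())
  pc3 <- PathwayCollection(setNames(lapply(ps, `[[`, "m"), paste0("p", 1:3)),
                           setNames(lapply(ps, `[[`, "e"), paste0("p", 1:3)))
  net3 <- mergeNetwork(pc3)
  allE <- do.call(rbind, lapply(ps, `[[`, "e"))
  key <- unique(apply(allE, 1, function(r) paste(sort(r), collapse = "|")))
  expect_equal(igraph::ecount(net3@graph), length(key))
  touched <- unique(c(allE))
  expect_setequal(nodeNames(net3), touched)
  expect_setequal(singletons(net3),
                  setdiff(unique(unlist(lapply(ps, `[[`, "m"))), touched))

  # degree-sum identity
  expect_equal(sum(degrees(net3)), 2 * igraph::ecount(net3@graph))
})

test_that("hubs are nodes with degree strictly above the threshold", {
  mkStar <- function(k) annotateTopology(mergeNetwork(starCollection(k)))
  net30 <- mkStar(30)
  expect_true(isHub(net30)[["hub"]])
  net20 <- mkStar(20)
  expect_false(isHub(net20)[["hub"]])
  net21 <- mkStar(21)
  expect_true(isHub(net21)[["hub"]])

  # K_{1,5}: center neighborhood connectivity 1, leaves 5
  net5 <- mkStar(5)
  nc <- setNames(net5@nodeData$neighborhood_connectivity,
                 rownames(net5@nodeData))
  expect_equal(unname(nc["hub"]), 1)
  expect_equal(unname(nc["leaf3"]), 5)

  # hub set shrinks monotonically in the threshold
  pc <- starCollection(25)
  hubs <- vapply(c(5, 10, 20, 24, 25), function(thr)
    sum(isHub(annotateTopology(mergeNetwork(pc), thr))), numeric(1))
  expect_true(all(diff(hubs) <= 0))
})

test_that("module exclusion removes nodes and re-derives topology", {
  pc <- starCollection(25)
  net <- annotateTopology(mergeNetwork(pc))
  expect_identical(excludeGeneModule(net, character(0)), net)

  # removing most leaves demotes the center below the hub threshold
  cut <- excludeGeneModule(net, sprintf("leaf%d", 1:20))
  expect_false(isHub(cut)[["hub"]])
  expect_equal(sum(degrees(cut)), 2 * igraph::ecount(cut@graph))
  expect_warning(excludeGeneModule(net, "ghost"), "ghost")

  # removing a 5-clique drops exactly 10 edges
  cl <- t(combn(paste0("c", 1:5), 2))
  pc2 <- PathwayCollection(list(k5 = paste0("c", 1:5), star = c("hub", "x")),
                           list(k5 = cl, star = cbind("hub", "x")))
  net2 <- annotateTopology(mergeNetwork(pc2))
  before <- igraph::ecount(net2@graph)
  after <- igraph::ecount(excludeGeneModule(net2, paste0("c", 1:5))@graph)
  expect_equal(before - after, 10)
})

test_that("degree ECDFs are proper distribution functions", {
  pc <- starCollection(5)
  net <- annotateTopology(mergeNetwork(pc))
  deStatus(net) <- c(hub = "up")
  one <- degreeEcdf(net, "DE")
  expect_equal(one$degree, 5)
  expect_equal(one$cumfrac, 1)

  # 8-node fixture against sort-and-count (and stats::ecdf)
  edges <- rbind(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"),
                 c("e", "f"), c("g", "h"))
  net8 <- annotateTopology(mergeNetwork(edgeCollection(edges)))
  deStatus(net8) <- setNames(rep("down", 3), c("a", "e", "g"))
  curve <- degreeEcdf(net8, "nonDE")
  degs <- igraph::degree(net8@graph)[c("b", "c", "d", "f", "h")]
  ref <- stats::ecdf(degs)
  expect_true(all(diff(curve$cumfrac) >= 0))
  expect_equal(curve$cumfrac[length(curve$cumfrac)], 1)
  expect_equal(curve$cumfrac, ref(curve$degree))
  expect_error(degreeEcdf(annotateTopology(mergeNetwork(starCollection(3))),
                          "DE"), "no DE")
})

test_that("network overlap matches ids through the homology map", {
  pcA <- edgeCollection(rbind(c("a1", "a2"), c("a2", "a3")))
  pcB <- edgeCollection(rbind(c("b1", "b2"), c("b2", "b4")))
  netA <- annotateTopology(mergeNetwork(pcA))
  netB <- annotateTopology(mergeNetwork(pcB))
  map <- methods::new("HomologyMap", pairs = data.frame(
    geneA = paste0("a", 1:3), geneB = paste0("b", 1:3),
    scoreAB = 200, scoreBA = 200))
  ov <- networkOverlap(netA, netB, map)
  expect_equal(ov$sharedNodes, 2)  # a1->b1, a2->b2 present; b3 absent

  # identical networks overlap fully; disjoint not at all
  self <- networkOverlap(netA, netA)
  expect_equal(self$percentA, 100)
  expect_equal(self$percentB, 100)
  expect_equal(networkOverlap(netA, netB)$sharedNodes, 0)
})

test_that("percent reporting rounds half up to integers", {
  expect_equal(reportPercent(3156, 3305), 95)
  expect_equal(reportPercent(3156, 3561), 89)
  expect_equal(roundHalfUp(0.5), 1)
  expect_equal(roundHalfUp(2.5), 3)
})

test_that("re-selection with the same DE set is idempotent", {
  set.seed(13)
  cfg <- tinyConfig(2)
  ds <- simulateDataset(cfg)
  de <- names(which(ds$truth@deLabelsA != "none"))
  sel1 <- selectPathways(ds$pathwaysA, de)
  sel2 <- selectPathways(sel1, de)
  expect_identical(members(sel1), members(sel2))
  n1 <- mergeNetwork(sel1)
  n2 <- mergeNetwork(sel2)
  expect_identical(nodeNames(n1), nodeNames(n2))
  expect_equal(igraph::ecount(n1@graph), igraph::ecount(n2@graph))
})
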