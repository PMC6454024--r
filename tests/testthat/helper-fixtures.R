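# Small in-code fixtures shared across test files.

# count matrix with explicit totals; one control and one treated sample
makeCounts <- function(ctl, trt, genes = sprintf("g%02d", seq_along(ctl))) {
  m <- cbind(ctl = as.integer(ctl), trt = as.integer(trt))
  rownames(m) <- genes
  CountMatrix(m, c("control", "treated"))
}

# star graph K_{1,k}: center "hub" connected to k leaves
starCollection <- function(k = 5) {
  leaves <- sprintf("leaf%d", seq_len(k))
  PathwayCollection(list(star = c("hub", leaves)),
                    list(star = cbind("hub", leaves)))
}

# pathway collection from an explicit global edge list (one pathway)
edgeCollection <- function(edges, extraMembers = character(0)) {
  memb <- unique(c(c(edges), extraMembers))
  PathwayCollection(list(p1 = memb), list(p1 = edges))
}

# independent BFS oracle: nodes within `radius` hops of any seed, via
# boolean adjacency-matrix expansion (no igraph)
bfsOracle <- function(edges, nodes, seeds, radius) {
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges[i, 1], edges[i, 2]] <- TRUE
    A[edges[i, 2], edges[i, 1]] <- TRUE
  }
  frontier <- nodes %in% seeds
  reached <- frontier
  for (r in seq_len(radius)) {
    frontier <- as.vector(A %*% frontier) > 0 & !reached
    reached <- reached | frontier
  }
  sort(setdiff(nodes[reached], seeds))
}

# tiny two-species dataset for pipeline-level tests
tinyConfig <- function(seed = 1, ...) {
  simulationConfig(nGenes = 120, nPathways = 10,
                   pathwaySizeRange = c(6, 12), edgeDensity = 0.25,
                   rngSeed = seed, ...)
}
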