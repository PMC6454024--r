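#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Raw count matrix for one species
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' single assay `"counts"` of non-negative integer read counts (genes in rows,
#' samples in columns) together with a `condition` column in `colData` taking
#' values `"control"` or `"treated"`.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [CountMatrix()] for the constructor, [filterLowCounts()],
#'   [estimateSizeFactors()].
#' @export
setClass("CountMatrix", contains = "SummarizedExperiment")

setValidity("CountMatrix", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(m)) || any(m < 0))
      msg <- c(msg, "counts must be non-negative and non-missing")
    if (any(m != round(m)))
      msg <- c(msg, "counts must be integers")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'condition' column")
  else {
    cond <- SummarizedExperiment::colData(object)$condition
    if (!all(cond %in% c("control", "treated")))
      msg <- c(msg, "condition must be 'control' or 'treated'")
  }
  if (length(msg)) msg else TRUE
})

#' Named collection of pathways with intra-pathway interactions
#'
#' Mirrors a GMT membership file plus a SIF edge file: each pathway is a set
#' of member gene ids and an undirected edge list between those members.
#'
#' @slot members named list of character vectors (pathway id -> member ids).
#' @slot edges named list of two-column character matrices, parallel to
#'   `members`; endpoints must be members of the same pathway, no self-loops.
#' @seealso [PathwayCollection()], [readPathwayCollection()],
#'   [selectPathways()], [mergeNetwork()].
#' @export
setClass("PathwayCollection",
  representation(members = "list", edges = "list"))

setValidity("PathwayCollection", function(object) {
  msg <- character(0)
  if (!identical(names(object@members), names(object@edges)))
    msg <- c(msg, "members and edges must share pathway names")
  if (length(object@members) && is.null(names(object@members)))
    msg <- c(msg, "pathways must be named")
  if (anyDuplicated(names(object@members)))
    msg <- c(msg, "duplicate pathway ids")
  for (p in names(object@members)) {
    e <- object@edges[[p]]
    if (!is.matrix(e) || ncol(e) != 2) {
      msg <- c(msg, sprintf("edges of '%s' must be a 2-column matrix", p))
      next
    }
    if (nrow(e)) {
      if (!all(c(e) %in% object@members[[p]]))
        msg <- c(msg, sprintf("edge endpoints of '%s' outside membership", p))
      if (any(e[, 1] == e[, 2]))
        msg <- c(msg, sprintf("self-loop in pathway '%s'", p))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Merged functional-interaction network
#'
#' Deduplicated undirected union of the interaction graphs of a pathway
#' collection. The connected part lives in an igraph object; members that
#' carry no interaction at all are kept aside as singletons and excluded from
#' degree-based statistics. Node attributes (`de_status`, `degree`, `is_hub`,
#' `neighborhood_connectivity`) are stored in a parallel `DataFrame`.
#'
#' @slot graph igraph object, simple and undirected.
#' @slot nodeData [S4Vectors::DataFrame] with one row per graph vertex.
#' @slot singletons character vector of zero-degree member ids.
#' @slot hubThreshold numeric; hubs have degree strictly greater than this.
#' @slot pathwayIds ids of the pathways merged into the network.
#' @seealso [mergeNetwork()], [annotateTopology()], [degreeEcdf()],
#'   [networkOverlap()].
#' @export
setClass("MergedNetwork",
  representation(graph = "ANY", nodeData = "DataFrame",
                 singletons = "character", hubThreshold = "numeric",
                 pathwayIds = "character"))

setValidity("MergedNetwork", function(object) {
  msg <- character(0)
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (!igraph::is_simple(g)) msg <- c(msg, "graph must be simple")
  vn <- igraph::V(g)$name
  rn <- rownames(object@nodeData)
  if (!identical(as.character(rn %||% character(0)),
                 as.character(vn %||% character(0))))
    msg <- c(msg, "nodeData rows must match graph vertices")
  if (length(intersect(object@singletons, igraph::V(g)$name)))
    msg <- c(msg, "singletons must not appear in the graph")
  if ("degree" %in% colnames(object@nodeData)) {
    if (!identical(as.integer(object@nodeData$degree),
                   as.integer(igraph::degree(g))))
      msg <- c(msg, "stored degrees disagree with the graph")
  }
  if (length(msg)) msg else TRUE
})

#' One-to-one cross-species homology map
#'
#' Gene pairs supported by mutual best similarity hits, with the two
#' supporting bit-scores. Each gene of either species appears at most once.
#'
#' @slot pairs data.frame with columns `geneA`, `geneB`, `scoreAB`, `scoreBA`.
#' @seealso [bestReciprocalHits()], [compareDESets()].
#' @export
setClass("HomologyMap", representation(pairs = "data.frame"))

setValidity("HomologyMap", function(object) {
  p <- object@pairs
  msg <- character(0)
  need <- c("geneA", "geneB", "scoreAB", "scoreBA")
  if (!all(need %in% colnames(p)))
    return(paste("pairs must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(p$geneA)) msg <- c(msg, "a geneA appears more than once")
  if (anyDuplicated(p$geneB)) msg <- c(msg, "a geneB appears more than once")
  if (length(msg)) msg else TRUE
})

#' Result of the neighborhood DE-enrichment permutation test
#'
#' @slot seeds seed node ids.
#' @slot radius neighborhood radius in edges.
#' @slot neighborhoodSize number of nodes at distance 1..radius of any seed
#'   (seeds excluded).
#' @slot observedDE observed count of DE nodes in the neighborhood.
#' @slot nullMean,nullSd mean and (n-1)-denominator standard deviation of the
#'   permutation null.
#' @slot z standardized score `(observed - nullMean)/nullSd` (`NA` when the
#'   null is degenerate).
#' @slot pNormal two-sided standard-normal tail probability of `z`.
#' @slot pEmpirical two-sided empirical permutation p with add-one correction.
#' @slot nPerm number of label permutations.
#' @slot rngSeed integer seed that generated the permutations.
#' @slot restrictedToHubs whether labels and counts were restricted to hubs.
#' @slot degenerate TRUE when the null standard deviation is zero.
#' @seealso [neighborhoodDETest()].
#' @export
setClass("NeighborhoodTestResult",
  representation(seeds = "character", radius = "integer",
                 neighborhoodSize = "integer", observedDE = "integer",
                 nullMean = "numeric", nullSd = "numeric", z = "numeric",
                 pNormal = "numeric", pEmpirical = "numeric",
                 nPerm = "integer", rngSeed = "integer",
                 restrictedToHubs = "logical", degenerate = "logical"))

setValidity("NeighborhoodTestResult", function(object) {
  msg <- character(0)
  if (object@observedDE < 0 || object@observedDE > object@neighborhoodSize)
    msg <- c(msg, "observedDE must lie in [0, neighborhoodSize]")
  for (p in c(object@pNormal, object@pEmpirical))
    if (!is.na(p) && (p < 0 || p > 1)) msg <- c(msg, "p values must be in [0,1]")
  if (!object@degenerate && object@nullSd > 0) {
    zz <- (object@observedDE - object@nullMean) / object@nullSd
    if (abs(zz - object@z) > 1e-8) msg <- c(msg, "z inconsistent with null moments")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic two-species study
#'
#' Defines the simulated design: a treated-vs-control contrast without
#' replicates in two species linked by a complete one-to-one homolog map,
#' negative-binomial counts with log-normal baseline means, a planted DE gene
#' set with effect sizes of `deLfcMagnitude` log2 units, a random pathway
#' collection in which the seed genes are hubs, optional DE enrichment of the
#' seeds' radius-2 neighborhood, and a noisy reciprocal hit table.
#'
#' @slot nGenes genes per species.
#' @slot nSamplesPerCondition samples per condition (1 = the no-replicate
#'   design the pipeline targets).
#' @slot nbMeanLogMu,nbMeanLogSigma meanlog/sdlog of the log-normal baseline
#'   gene means.
#' @slot nbDispersion negative-binomial dispersion (variance = mu + disp*mu^2).
#' @slot deFraction fraction of genes planted DE per species.
#' @slot deLfcMagnitude absolute planted log2 fold change.
#' @slot nPathways number of pathways.
#' @slot pathwaySizeRange inclusive integer range of pathway sizes.
#' @slot edgeDensity probability of an edge between two members of a pathway.
#' @slot seedGenes species-A ids to plant as hubs (empty = no planting).
#' @slot seedTargetDegree minimum merged degree of each seed (> 20 so that
#'   seeds are hubs under the default hub threshold).
#' @slot neighborhoodEnrichProb probability that a neighborhood node is
#'   relabeled DE.
#' @slot decoyHitFraction expected decoy hits per true pair in the hit table.
#' @slot rngSeed integer driving all randomness.
#' @seealso [simulationConfig()], [simulateDataset()].
#' @export
setClass("SimulationConfig",
  representation(nGenes = "integer", nSamplesPerCondition = "integer",
                 nbMeanLogMu = "numeric", nbMeanLogSigma = "numeric",
                 nbDispersion = "numeric", deFraction = "numeric",
                 deLfcMagnitude = "numeric", nPathways = "integer",
                 pathwaySizeRange = "integer", edgeDensity = "numeric",
                 seedGenes = "character", seedTargetDegree = "integer",
                 neighborhoodEnrichProb = "numeric",
                 decoyHitFraction = "numeric", rngSeed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (object@nSamplesPerCondition < 1L)
    msg <- c(msg, "nSamplesPerCondition must be positive")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
  for (f in c("deFraction", "neighborhoodEnrichProb", "decoyHitFraction")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0,1]", f))
  }
  if (object@deLfcMagnitude <= 0) msg <- c(msg, "deLfcMagnitude must be > 0")
  if (object@nPathways < 0L) msg <- c(msg, "nPathways must be non-negative")
  if (length(object@pathwaySizeRange) != 2L ||
      object@pathwaySizeRange[1] < 2L ||
      object@pathwaySizeRange[1] > object@pathwaySizeRange[2])
    msg <- c(msg, "pathwaySizeRange must be an increasing pair >= 2")
  if (object@edgeDensity <= 0 || object@edgeDensity > 1)
    msg <- c(msg, "edgeDensity must be in (0,1]")
  if (object@seedTargetDegree <= 20L)
    msg <- c(msg, "seedTargetDegree must exceed 20")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic dataset
#'
#' @slot deLabelsA,deLabelsB named character vectors over each species' genes
#'   with values `"up"`, `"down"` or `"none"`.
#' @slot homologPairs data.frame (`geneA`, `geneB`) of the true one-to-one map.
#' @slot plantedNeighborhood species-A ids forming the seeds' radius-2
#'   neighborhood (seeds excluded).
#' @slot seedGenes the planted seed ids.
#' @export
setClass("SyntheticTruth",
  representation(deLabelsA = "character", deLabelsB = "character",
                 homologPairs = "data.frame",
                 plantedNeighborhood = "character", seedGenes = "character"))

setValidity("SyntheticTruth", function(object) {
  msg <- character(0)
  if (length(intersect(object@plantedNeighborhood, object@seedGenes)))
    msg <- c(msg, "plantedNeighborhood must exclude the seeds")
  if (anyDuplicated(object@homologPairs$geneA) ||
      anyDuplicated(object@homologPairs$geneB))
    msg <- c(msg, "homolog pairs must be one-to-one")
  ok <- c("up", "down", "none")
  if (!all(object@deLabelsA %in% ok) || !all(object@deLabelsB %in% ok))
    msg <- c(msg, "DE labels must be up/down/none")
  if (length(msg)) msg else TRUE
})
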