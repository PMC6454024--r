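## Synthetic two-species datasets with known ground truth. The generator
## emulates the study design the pipeline targets: a single treated and a
## single control library per species (no replicates), negative-binomial
## counts with log-normal baseline means, planted DE genes at a fixed |log2
## fold change|, a complete one-to-one homolog map, a KEGG-like pathway
## collection in which designated seed genes are hubs whose radius-2
## neighborhood can be enriched in DE labels, and a noisy reciprocal hit
## table feeding the homology module. One integer seed drives everything;
## identical configs reproduce identical datasets.

#' Build a simulation configuration
#'
#' See [SimulationConfig-class] for the meaning of every field. Defaults
#' describe the emulated study: ~5% DE genes at |log2FC| 1.5, one library
#' per condition, 25 pathways of 10-30 genes with intra-pathway edge density
#' 0.15, seed hubs pushed to merged degree >= 25, and 70% DE enrichment of
#' their radius-2 neighborhood when seeds are given.
#'
#' @param nGenes,nSamplesPerCondition,nbMeanLogMu,nbMeanLogSigma,nbDispersion
#'   expression model; see [SimulationConfig-class].
#' @param deFraction,deLfcMagnitude planted DE set; `floor(deFraction *
#'   nGenes)` genes are planted per species.
#' @param nPathways,pathwaySizeRange,edgeDensity pathway collection.
#' @param seedGenes,seedTargetDegree,neighborhoodEnrichProb planted hub seeds
#'   (species-A ids); empty `seedGenes` disables planting.
#' @param decoyHitFraction,rngSeed hit-table noise and the master seed.
#' @return a validated [SimulationConfig-class].
#' @examples
#' simulationConfig(nGenes = 200, seedGenes = c("gA0001", "gA0002"))
#' @export
simulationConfig <- function(nGenes = 400, nSamplesPerCondition = 1,
                             nbMeanLogMu = 5.5, nbMeanLogSigma = 1,
                             nbDispersion = 0.05, deFraction = 0.05,
                             deLfcMagnitude = 1.5, nPathways = 25,
                             pathwaySizeRange = c(10, 30),
                             edgeDensity = 0.15,
                             seedGenes = character(0),
                             seedTargetDegree = 25,
                             neighborhoodEnrichProb = 0.7,
                             decoyHitFraction = 0.2, rngSeed = 1) {
  methods::new("SimulationConfig",
    nGenes = as.integer(nGenes),
    nSamplesPerCondition = as.integer(nSamplesPerCondition),
    nbMeanLogMu = nbMeanLogMu, nbMeanLogSigma = nbMeanLogSigma,
    nbDispersion = nbDispersion, deFraction = deFraction,
    deLfcMagnitude = deLfcMagnitude, nPathways = as.integer(nPathways),
    pathwaySizeRange = as.integer(pathwaySizeRange),
    edgeDensity = edgeDensity, seedGenes = as.character(seedGenes),
    seedTargetDegree = as.integer(seedTargetDegree),
    neighborhoodEnrichProb = neighborhoodEnrichProb,
    decoyHitFraction = decoyHitFraction, rngSeed = as.integer(rngSeed))
}

#' Species-A / species-B gene identifiers of a configuration
#'
#' @param config a [SimulationConfig-class].
#' @param species `"A"` or `"B"`.
#' @return character vector of `nGenes` ids (`gA0001...` / `gB0001...`).
#' @export
geneUniverse <- function(config, species = c("A", "B")) {
  species <- match.arg(species)
  sprintf("g%s%04d", species, seq_len(config@nGenes))
}

## draw an NB count matrix: rows = genes (means mu), columns = samples
.nbDraw <- function(mu, nSamples, dispersion) {
  matrix(stats::rnbinom(length(mu) * nSamples, mu = rep(mu, nSamples),
                        size = 1 / dispersion),
         nrow = length(mu), ncol = nSamples)
}

## random up/down/none labels: exactly nDE genes DE, signs uniform
.plantLabels <- function(ids, nDE) {
  lab <- stats::setNames(rep("none", length(ids)), ids)
  if (nDE > 0) {
    de <- sample(ids, nDE)
    lab[de] <- sample(c("up", "down"), nDE, replace = TRUE)
  }
  lab
}

.lfcSign <- function(label) c(up = 1, down = -1, none = 0)[label]

## counts for one species given baseline means and labels
.speciesCounts <- function(ids, baseline, labels, config, speciesTag) {
  ns <- config@nSamplesPerCondition
  muT <- baseline * 2^(unname(.lfcSign(labels[ids])) * config@deLfcMagnitude)
  m <- cbind(.nbDraw(baseline, ns, config@nbDispersion),
             .nbDraw(muT, ns, config@nbDispersion))
  dimnames(m) <- list(ids, c(sprintf("%s_ctl_%d", speciesTag, seq_len(ns)),
                             sprintf("%s_trt_%d", speciesTag, seq_len(ns))))
  CountMatrix(m, rep(c("control", "treated"), each = ns))
}

#' Simulate two-species expression with planted DE genes
#'
#' Draws, for each species, log-normal baseline means and negative-binomial
#' counts for `nSamplesPerCondition` control and treated libraries. Exactly
#' `floor(deFraction * nGenes)` genes per species are planted DE: their
#' treated mean is `2^(+/- deLfcMagnitude)` times the control mean, with
#' signs chosen uniformly. The two species' DE sets are planted
#' independently; homology is the index-matched one-to-one pairing.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `countsA`, `countsB` ([CountMatrix-class]), `truth`
#'   ([SyntheticTruth-class], neighborhood fields empty at this stage) and
#'   `baselineA`/`baselineB` (the configured NB control means, useful for
#'   checking count marginals).
#' @export
simulateExpression <- function(config) {
  methods::validObject(config)
  idsA <- geneUniverse(config, "A")
  idsB <- geneUniverse(config, "B")
  nDE <- floor(config@deFraction * config@nGenes)
  withSeed(deriveSeed(config@rngSeed, 1L), {
    baseA <- stats::rlnorm(config@nGenes, config@nbMeanLogMu,
                           config@nbMeanLogSigma)
    baseB <- stats::rlnorm(config@nGenes, config@nbMeanLogMu,
                           config@nbMeanLogSigma)
    labA <- .plantLabels(idsA, nDE)
    labB <- .plantLabels(idsB, nDE)
    countsA <- .speciesCounts(idsA, baseA, labA, config, "a")
    countsB <- .speciesCounts(idsB, baseB, labB, config, "b")
    truth <- methods::new("SyntheticTruth",
      deLabelsA = labA, deLabelsB = labB,
      homologPairs = data.frame(geneA = idsA, geneB = idsB,
                                stringsAsFactors = FALSE),
      plantedNeighborhood = character(0),
      seedGenes = character(0))
    list(countsA = countsA, countsB = countsB, truth = truth,
         baselineA = stats::setNames(baseA, idsA),
         baselineB = stats::setNames(baseB, idsB))
  })
}

## Erdos-Renyi edges among `memb` at density p, as a 2-column matrix
.erEdges <- function(memb, p) {
  if (length(memb) < 2) return(matrix(character(0), 0, 2))
  pairs <- t(utils::combn(memb, 2))
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}

#' Simulate a pathway collection with planted seed hubs
#'
#' Generates `nPathways` pathways with memberships drawn from the species-A
#' gene universe and random intra-pathway edges at `edgeDensity`. Each seed
#' gene is then inserted into pathways (connecting it to their members)
#' until its merged-network degree reaches `seedTargetDegree`; an error is
#' raised when the collection cannot support that degree. Finally the DE
#' labels of the seeds' radius-2 neighborhood in the merged network are
#' rewritten: each neighborhood node becomes DE (random sign) with
#' probability `neighborhoodEnrichProb`, otherwise keeps its background
#' label, and the truth is updated accordingly. Edges are stored with
#' induced-subgraph semantics: an interaction belongs to every pathway whose
#' membership contains both endpoints (as in curated pathway databases), so
#' GMT+SIF round-trips are lossless.
#'
#' @param config a [SimulationConfig-class].
#' @param geneUniverse character vector of species-A gene ids.
#' @param truth the [SyntheticTruth-class] to update.
#' @return list with `collection` ([PathwayCollection-class]) and the
#'   updated `truth`.
#' @export
simulatePathwayCollection <- function(config, geneUniverse, truth) {
  if (!all(config@seedGenes %in% geneUniverse))
    stop("seed genes outside the gene universe")
  if (config@nPathways == 0L)
    return(list(collection = PathwayCollection(
      stats::setNames(list(), character(0)),
      stats::setNames(list(), character(0))), truth = truth))
  withSeed(deriveSeed(config@rngSeed, 2L), {
    sizes <- sample(seq(config@pathwaySizeRange[1],
                        config@pathwaySizeRange[2]),
                    config@nPathways, replace = TRUE)
    ids <- sprintf("path%03d", seq_len(config@nPathways))
    membs <- lapply(sizes, function(s) sample(geneUniverse, s))
    names(membs) <- ids
    edges <- lapply(membs, .erEdges, p = config@edgeDensity)

    ## plant each seed as a hub: walk pathways in random order, join and
    ## wire the seed to all members until the merged degree target is met
    for (s in config@seedGenes) {
      nb <- unique(unlist(mapply(function(m, e) {
        c(if (s %in% m) setdiff(c(e[e[, 1] == s, 2], e[e[, 2] == s, 1]), s))
      }, membs, edges, SIMPLIFY = FALSE), use.names = FALSE))
      for (p in sample(ids)) {
        if (length(nb) >= config@seedTargetDegree) break
        new <- setdiff(membs[[p]], c(s, nb))
        if (!length(new)) next
        if (!(s %in% membs[[p]])) membs[[p]] <- c(membs[[p]], s)
        edges[[p]] <- rbind(edges[[p]], cbind(s, new))
        nb <- c(nb, new)
      }
      if (length(nb) < config@seedTargetDegree)
        stop("seedTargetDegree unattainable with this pathway configuration")
    }

    ## induced-subgraph edge semantics: each deduplicated interaction is
    ## carried by every pathway containing both endpoints
    allE <- do.call(rbind, unname(edges))
    flip <- allE[, 1] > allE[, 2]
    allE[flip, ] <- allE[flip, c(2, 1), drop = FALSE]
    allE <- allE[!duplicated(paste(allE[, 1], allE[, 2], sep = "\r")), ,
                 drop = FALSE]
    edges <- lapply(membs, function(m) {
      allE[allE[, 1] %in% m & allE[, 2] %in% m, , drop = FALSE]
    })
    collection <- PathwayCollection(membs, edges)

    ## relabel the seeds' radius-2 neighborhood
    if (length(config@seedGenes)) {
      net <- mergeNetwork(collection)
      nbhd <- extractNeighborhood(net, config@seedGenes, radius = 2)
      hit <- nbhd[stats::runif(length(nbhd)) < config@neighborhoodEnrichProb]
      lab <- truth@deLabelsA
      lab[hit] <- sample(c("up", "down"), length(hit), replace = TRUE)
      truth@deLabelsA <- lab
      truth@plantedNeighborhood <- nbhd
      truth@seedGenes <- config@seedGenes
      methods::validObject(truth)
    }
    list(collection = collection, truth = truth)
  })
}

#' Simulate reciprocal similarity hit tables
#'
#' Every true homolog pair receives a mutual pair of hits with bit-scores
#' well above the filtering threshold (uniform on 150-400). Decoy hits --
#' `floor(decoyHitFraction * nPairs)` per direction -- point a random query
#' at a random wrong subject with a weaker score (uniform on 60-200, so a
#' small fraction outrank a true hit and depress recall without ever forming
#' a reciprocal pair). When decoys are present, one of them is pinned to
#' bit-score 99 so the strict `>= 100` filter boundary is always exercised.
#'
#' @param truth a [SyntheticTruth-class] with the true pairs.
#' @param config a [SimulationConfig-class].
#' @return list with hit tables `ab` (A queries vs B subjects) and `ba`.
#' @export
simulateHitTable <- function(truth, config) {
  pairs <- truth@homologPairs
  if (!nrow(pairs) && config@decoyHitFraction < 1)
    stop("no true homolog pairs to simulate hits from")
  withSeed(deriveSeed(config@rngSeed, 3L), {
    n <- nrow(pairs)
    qlenA <- sample(500:3000, n, replace = TRUE)
    qlenB <- sample(500:3000, n, replace = TRUE)
    alen <- pmin(qlenA, qlenB) - sample(0:100, n, replace = TRUE)
    ## bit-scores carry one decimal, like the tabular output they emulate
    ab <- hitTable(pairs$geneA, pairs$geneB,
                   round(stats::runif(n, 150, 400), 1), alen, qlenA)
    ba <- hitTable(pairs$geneB, pairs$geneA,
                   round(stats::runif(n, 150, 400), 1), alen, qlenB)
    nDecoy <- floor(config@decoyHitFraction * n)
    mkDecoys <- function(qIds, sIds, qlen) {
      if (nDecoy < 1) return(NULL)
      qi <- sample(n, nDecoy, replace = TRUE)
      ## a wrong subject: shift the index so decoys never match the truth
      si <- (qi + sample(n - 1, nDecoy, replace = TRUE) - 1L) %% n + 1L
      sc <- round(stats::runif(nDecoy, 60, 200), 1)
      sc[1] <- 99           # pin one decoy right under the score filter
      hitTable(qIds[qi], sIds[si], sc,
               pmax(50L, as.integer(qlen[qi] * 0.3)), qlen[qi])
    }
    dab <- mkDecoys(pairs$geneA, pairs$geneB, qlenA)
    dba <- mkDecoys(pairs$geneB, pairs$geneA, qlenB)
    if (!is.null(dab)) ab <- rbind(ab, dab)
    if (!is.null(dba)) ba <- rbind(ba, dba)
    rownames(ab) <- rownames(ba) <- NULL
    list(ab = ab, ba = ba)
  })
}

#' Simulate a complete two-species dataset
#'
#' Orchestrates [simulateExpression()], [simulatePathwayCollection()] (over
#' the species-A universe) and [simulateHitTable()], then (i) re-draws the
#' treated counts of any species-A gene whose label changed during
#' neighborhood planting so expression-derived DE calls agree with the
#' truth, and (ii) expresses the same pathway topology in species-B ids
#' through the homolog map, mirroring a shared pathway database annotated in
#' each species' namespace.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `countsA`, `countsB`, `pathwaysA`, `pathwaysB`,
#'   `hitsAB`, `hitsBA`, `truth`, `config`.
#' @export
simulateDataset <- function(config) {
  ex <- simulateExpression(config)
  pc <- simulatePathwayCollection(config, geneUniverse(config, "A"),
                                  ex$truth)
  truth <- pc$truth
  ## re-sync species-A treated counts with relabeled genes
  changed <- names(which(truth@deLabelsA != ex$truth@deLabelsA))
  if (length(changed)) {
    m <- counts(ex$countsA)
    trt <- conditions(ex$countsA) == "treated"
    muT <- ex$baselineA[changed] *
      2^(unname(.lfcSign(truth@deLabelsA[changed])) * config@deLfcMagnitude)
    withSeed(deriveSeed(config@rngSeed, 4L), {
      m[changed, trt] <- .nbDraw(muT, sum(trt), config@nbDispersion)
    })
    ex$countsA <- CountMatrix(m, conditions(ex$countsA))
  }
  ## species-B collection: same topology, B namespace
  tr <- stats::setNames(truth@homologPairs$geneB, truth@homologPairs$geneA)
  rename <- function(x) unname(tr[x])
  pathwaysB <- PathwayCollection(
    lapply(members(pc$collection), rename),
    lapply(pathwayEdges(pc$collection), function(e) {
      matrix(rename(c(e)), ncol = 2)
    }))
  hits <- simulateHitTable(truth, config)
  list(countsA = ex$countsA, countsB = ex$countsB,
       pathwaysA = pc$collection, pathwaysB = pathwaysB,
       hitsAB = hits$ab, hitsBA = hits$ba,
       truth = truth, config = config)
}
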