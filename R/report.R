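## Pipeline orchestration and reporting: run the whole analysis from a
## config, emit a hub table partitioned by species specificity, a DE-overlap
## summary, a fold-change heatmap matrix, and a simplified GO-term-profile
## contrast between the two species' DE lists.

#' Build a pipeline configuration
#'
#' Thin validated container of input paths and thresholds for
#' [runPipeline()]. All thresholds default to the pipeline's canonical
#' values: low-count filter 50, |log2FC| threshold 1, bit-score filter 100,
#' hub threshold 20, neighborhood radius 2, 1000 permutations.
#'
#' @param dataDir directory holding a dataset laid out as by
#'   [writeDataset()].
#' @param outDir output directory for the report bundle.
#' @param seeds seed node ids (species-A namespace) for the neighborhood
#'   test; empty disables that stage.
#' @param minTotal,lfcThreshold,minBitscore,hubThreshold,radius,nPerm
#'   stage thresholds.
#' @param rngSeed integer seed for the permutation test.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(dataDir, outDir, seeds = character(0),
                           minTotal = 50, lfcThreshold = 1,
                           minBitscore = 100, hubThreshold = 20,
                           radius = 2, nPerm = 1000, rngSeed = 1) {
  stopifnot(minTotal > 0, lfcThreshold > 0, minBitscore > 0,
            hubThreshold > 0, radius > 0, nPerm >= 2)
  cfg <- list(dataDir = dataDir, outDir = outDir,
              seeds = as.character(seeds), minTotal = minTotal,
              lfcThreshold = lfcThreshold, minBitscore = minBitscore,
              hubThreshold = hubThreshold, radius = as.integer(radius),
              nPerm = as.integer(nPerm), rngSeed = as.integer(rngSeed))
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full cross-species pipeline
#'
#' Executes, per species, expression analysis (filter, size factors, fold
#' change, DE call), then homology mapping from the reciprocal hit tables,
#' pathway selection and network merging per species, topology annotation,
#' the neighborhood permutation test (when seeds are configured) and report
#' writing. Every artifact lands in `config$outDir` together with a
#' `manifest.json` recording package version, seed, thresholds and input
#' checksums; given the same inputs and `rngSeed`, reruns are byte
#' identical.
#'
#' @param config a [pipelineConfig()] object.
#' @return invisibly, a list with the in-memory results (`tableA`, `tableB`,
#'   `map`, `comparison`, `netA`, `netB`, `overlap`, `nbTest`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  for (f in c("counts_a.tsv", "counts_a_conditions.tsv", "counts_b.tsv",
              "counts_b_conditions.tsv", "pathways_a.gmt", "pathways_a.sif",
              "pathways_b.gmt", "pathways_b.sif", "hits_ab.tsv",
              "hits_ba.tsv"))
    if (!file.exists(file.path(config$dataDir, f)))
      stop("missing input file: ", file.path(config$dataDir, f))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  countsA <- .stage("read", readCountMatrix(file.path(config$dataDir,
                                                      "counts_a")))
  countsB <- .stage("read", readCountMatrix(file.path(config$dataDir,
                                                      "counts_b")))
  tableA <- .stage("expression A",
                   expressionTable(countsA, config$minTotal,
                                   config$lfcThreshold))
  tableB <- .stage("expression B",
                   expressionTable(countsB, config$minTotal,
                                   config$lfcThreshold))
  message(sprintf("expression: %d/%d genes kept (A), %d/%d (B); %d/%d DE",
                  nrow(tableA), nrow(countsA), nrow(tableB), nrow(countsB),
                  sum(tableA$de_status != "none"),
                  sum(tableB$de_status != "none")))

  hitsAB <- .stage("homology", filterHits(
    readHitTable(file.path(config$dataDir, "hits_ab.tsv")),
    config$minBitscore))
  hitsBA <- .stage("homology", filterHits(
    readHitTable(file.path(config$dataDir, "hits_ba.tsv")),
    config$minBitscore))
  map <- .stage("homology", bestReciprocalHits(hitsAB, hitsBA))
  ## genes dropped by the low-count filter have no DE call; restrict the
  ## comparison to pairs measurable in both species
  measurable <- local({
    p <- homologPairs(map)
    keep <- p$geneA %in% tableA$gene_id & p$geneB %in% tableB$gene_id
    methods::new("HomologyMap", pairs = p[keep, , drop = FALSE])
  })
  message(sprintf("homology: %d reciprocal pairs, %d measurable in both",
                  length(map), length(measurable)))
  cmp <- .stage("homology", compareDESets(measurable, tableA, tableB))

  buildNet <- function(pathPrefix, table, label) {
    pc <- readPathwayCollection(
      file.path(config$dataDir, paste0(pathPrefix, ".gmt")),
      file.path(config$dataDir, paste0(pathPrefix, ".sif")))
    de <- stats::setNames(table$de_status, table$gene_id)
    sel <- selectPathways(pc, names(de)[de != "none"])
    message(sprintf("network %s: %d/%d pathways selected", label,
                    length(sel), length(pc)))
    net <- mergeNetwork(sel, de)
    annotateTopology(net, config$hubThreshold)
  }
  netA <- .stage("network A", buildNet("pathways_a", tableA, "A"))
  netB <- .stage("network B", buildNet("pathways_b", tableB, "B"))
  overlap <- .stage("network overlap", networkOverlap(netA, netB, map))

  nbTest <- NULL
  if (length(config$seeds))
    nbTest <- .stage("neighborhood",
                     neighborhoodDETest(netA, config$seeds,
                                        radius = config$radius,
                                        nPerm = config$nPerm,
                                        rngSeed = config$rngSeed))

  ## ---- report bundle ----
  out <- function(f) file.path(config$outDir, f)
  .writeTSV(tableA, out("expression_a.tsv"))
  .writeTSV(tableB, out("expression_b.tsv"))
  .writeTSV(homologPairs(map), out("homology_map.tsv"))
  .writeTSV(cmp$pairs, out("de_comparison.tsv"))
  writeNetwork(netA, out("network_a.sif"), out("network_a_nodes.tsv"))
  writeNetwork(netB, out("network_b.sif"), out("network_b_nodes.tsv"))
  .writeTSV(hubReport(netA, netB, tableA, tableB, map), out("hubs.tsv"))
  .writeTSV(lfcHeatmapMatrix(cmp, tableA, tableB), out("heatmap_lfc.tsv"))

  summaryLines <- c(
    sprintf("de_genes_a: %d", sum(tableA$de_status != "none")),
    sprintf("de_genes_b: %d", sum(tableB$de_status != "none")),
    sprintf("homolog_pairs: %d", length(map)),
    sprintf("shared_de: %d", cmp$counts[["shared_de"]]),
    sprintf("concordant: %d",
            cmp$counts[["concordant_up"]] + cmp$counts[["concordant_down"]]),
    sprintf("network_a: %d nodes, %d edges, %d singletons, %d hubs",
            length(nodeNames(netA)), igraph::ecount(netA@graph),
            length(singletons(netA)), sum(isHub(netA))),
    sprintf("network_b: %d nodes, %d edges, %d singletons, %d hubs",
            length(nodeNames(netB)), igraph::ecount(netB@graph),
            length(singletons(netB)), sum(isHub(netB))),
    sprintf("shared_nodes: %d (%d%% of A, %d%% of B)",
            overlap$sharedNodes, overlap$percentA, overlap$percentB),
    sprintf("shared_pathways: %d", overlap$sharedPathways))
  if (!is.null(nbTest))
    summaryLines <- c(summaryLines,
      sprintf("neighborhood: seeds=%s size=%d observed_de=%d",
              paste(nbTest@seeds, collapse = ","),
              nbTest@neighborhoodSize, nbTest@observedDE),
      if (nbTest@degenerate) "neighborhood_test: degenerate null" else
        sprintf("neighborhood_test: z=%.4f p_normal=%.6f p_empirical=%.6f",
                nbTest@z, nbTest@pNormal, nbTest@pEmpirical))
  writeLines(summaryLines, out("summary.txt"))

  inputs <- sort(list.files(config$dataDir, full.names = TRUE))
  inputs <- inputs[utils::file_test("-f", inputs)]
  manifest <- list(
    package = "netcontrast",
    version = as.character(utils::packageVersion("netcontrast")),
    rng_seed = config$rngSeed,
    thresholds = config[c("minTotal", "lfcThreshold", "minBitscore",
                          "hubThreshold", "radius", "nPerm")],
    seeds = config$seeds,
    input_md5 = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                        basename(inputs))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(tableA = tableA, tableB = tableB, map = map,
                 comparison = cmp, netA = netA, netB = netB,
                 overlap = overlap, nbTest = nbTest))
}

#' Hub report partitioned by species specificity
#'
#' One row per node that is a hub in either species' network and DE in at
#' least one species, with both species' log2 fold changes, the degree and
#' neighborhood connectivity (taken from the network in which the node is a
#' hub; species A wins when both). Rows are partitioned into
#' `a_specific` / `both` / `b_specific` by where the DE call fires, and
#' sorted by degree (descending) within partitions.
#'
#' @param netA,netB annotated [MergedNetwork-class] objects.
#' @param tableA,tableB expression tables.
#' @param map optional [HomologyMap-class]; when given, species-B nodes and
#'   table rows are translated into the A namespace before joining.
#' @param lfcThreshold DE threshold used for the partition (default 1).
#' @return data.frame with columns `gene`, `log2fc_a`, `log2fc_b`, `degree`,
#'   `neighborhood_connectivity`, `partition`.
#' @export
hubReport <- function(netA, netB, tableA, tableB, map = NULL,
                      lfcThreshold = 1) {
  toA <- identity
  if (!is.null(map)) {
    tr <- stats::setNames(homologPairs(map)$geneA, homologPairs(map)$geneB)
    toA <- function(x) unname(tr[x])
  }
  hubsA <- names(which(isHub(netA)))
  hubsB <- toA(names(which(isHub(netB))))
  hubsB <- hubsB[!is.na(hubsB)]
  lfcA <- stats::setNames(tableA$log2fc, tableA$gene_id)
  lfcB <- stats::setNames(tableB$log2fc, toA(tableB$gene_id))
  allHubs <- union(hubsA, hubsB)
  la <- lfcA[allHubs]
  lb <- lfcB[allHubs]
  deA <- !is.na(la) & abs(la) >= lfcThreshold
  deB <- !is.na(lb) & abs(lb) >= lfcThreshold
  keep <- deA | deB
  part <- ifelse(deA & deB, "both", ifelse(deA, "a_specific", "b_specific"))
  degA <- degrees(netA)
  ncA <- stats::setNames(netA@nodeData$neighborhood_connectivity,
                         rownames(netA@nodeData))
  degB <- stats::setNames(unname(degrees(netB)), toA(names(degrees(netB))))
  ncB <- stats::setNames(netB@nodeData$neighborhood_connectivity,
                         toA(rownames(netB@nodeData)))
  deg <- ifelse(allHubs %in% names(degA), degA[allHubs], degB[allHubs])
  nc <- ifelse(allHubs %in% names(ncA), ncA[allHubs], ncB[allHubs])
  d <- data.frame(gene = allHubs, log2fc_a = unname(la),
                  log2fc_b = unname(lb), degree = unname(deg),
                  neighborhood_connectivity = unname(nc),
                  partition = unname(part),
                  stringsAsFactors = FALSE)[keep, , drop = FALSE]
  d <- d[order(match(d$partition, c("a_specific", "both", "b_specific")),
               -d$degree, d$gene), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Fold-change matrix for heatmap export
#'
#' Matrix of both species' log2 fold changes for the shared-DE homolog
#' pairs, grouped by sign pattern (concordant up, concordant down, opposite)
#' -- a plain-text stand-in for a clustered heatmap figure.
#'
#' @param cmp result of [compareDESets()].
#' @param tableA,tableB expression tables.
#' @return data.frame with `gene_a`, `gene_b`, `log2fc_a`, `log2fc_b`,
#'   `class`.
#' @export
lfcHeatmapMatrix <- function(cmp, tableA, tableB) {
  p <- cmp$pairs[cmp$pairs$class %in%
                 c("concordant_up", "concordant_down", "opposite"), ,
                 drop = FALSE]
  lfcA <- stats::setNames(tableA$log2fc, tableA$gene_id)
  lfcB <- stats::setNames(tableB$log2fc, tableB$gene_id)
  d <- data.frame(gene_a = p$geneA, gene_b = p$geneB,
                  log2fc_a = unname(lfcA[p$geneA]),
                  log2fc_b = unname(lfcB[p$geneB]),
                  class = p$class, stringsAsFactors = FALSE)
  d <- d[order(match(d$class, c("concordant_up", "concordant_down",
                                "opposite")), d$gene_a), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Term-usage profile of a gene list
#'
#' Counts, for every annotation term, how many genes of the list carry it.
#' A gene may contribute to several terms; genes without any annotation are
#' skipped and their number reported.
#'
#' @param annotations data.frame with columns `gene_id` and `term`.
#' @param geneList character vector of gene ids.
#' @return list of class `TermProfile`: `counts` (named integer vector over
#'   terms), `listSize`, `unannotated`.
#' @export
buildTermProfile <- function(annotations, geneList) {
  stopifnot(all(c("gene_id", "term") %in% colnames(annotations)))
  ann <- annotations[annotations$gene_id %in% geneList, , drop = FALSE]
  counts <- table(factor(ann$term, levels = sort(unique(annotations$term))))
  unann <- length(setdiff(geneList, annotations$gene_id))
  if (unann)
    message(unann, " gene(s) without annotation ignored")
  structure(list(counts = c(unclass(counts)),
                 listSize = length(geneList), unannotated = unann),
            class = "TermProfile")
}

#' Contrast two term profiles
#'
#' Per term, a 2x2 table (genes of list A vs list B, carrying vs not
#' carrying the term) is tested with Fisher's exact test, with
#' Benjamini-Hochberg adjustment across terms; a signed log2 ratio of
#' relative term usage (positive = A-leaning) is reported with a 0.5
#' smoothing count. Globally, a chi-square homogeneity test compares the two
#' term-count vectors, pooling terms with expected count below 1.
#'
#' @param pA,pB `TermProfile` objects (see [buildTermProfile()]) over a
#'   shared vocabulary.
#' @return list with `table` (per-term data.frame: counts, odds ratio,
#'   `p`, `q`, `log_ratio`) and `globalP`.
#' @export
compareProfiles <- function(pA, pB) {
  terms <- union(names(pA$counts), names(pB$counts))
  cA <- stats::setNames(rep(0L, length(terms)), terms)
  cB <- cA
  cA[names(pA$counts)] <- pA$counts
  cB[names(pB$counts)] <- pB$counts
  if (sum(cA) + sum(cB) == 0) stop("both term profiles are all zero")
  res <- lapply(terms, function(tm) {
    m <- matrix(c(cA[[tm]], pA$listSize - cA[[tm]],
                  cB[[tm]], pB$listSize - cB[[tm]]), 2, 2)
    ft <- stats::fisher.test(m)
    c(p = ft$p.value, or = unname(ft$estimate))
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  or <- vapply(res, `[[`, numeric(1), "or")
  logRatio <- log2(((cA + 0.5) / pA$listSize) / ((cB + 0.5) / pB$listSize))
  tab <- data.frame(term = terms, count_a = unname(cA), count_b = unname(cB),
                    odds_ratio = or, p = p,
                    q = stats::p.adjust(p, "BH"),
                    log_ratio = unname(logRatio), stringsAsFactors = FALSE)

  ## global homogeneity: pool terms whose expected count under the pooled
  ## margin falls below 1, then chi-square on the 2 x T table
  tot <- cA + cB
  expMin <- outer(c(sum(cA), sum(cB)) / sum(tot), tot)
  small <- apply(expMin < 1, 2, any)
  gA <- c(cA[!small], pooled = sum(cA[small]))
  gB <- c(cB[!small], pooled = sum(cB[small]))
  keep <- gA + gB > 0
  globalP <- if (sum(keep) < 2) 1 else
    suppressWarnings(stats::chisq.test(rbind(gA[keep], gB[keep]))$p.value)
  list(table = tab, globalP = globalP)
}
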