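#' Construct a CountMatrix
#'
#' @param counts integer matrix of raw read counts, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param condition character or factor, one of `"control"`/`"treated"` per
#'   sample.
#' @return A [CountMatrix-class] object.
#' @examples
#' m <- matrix(rpois(8, 100), 4, 2,
#'             dimnames = list(paste0("g", 1:4), c("ctl", "trt")))
#' cm <- CountMatrix(m, c("control", "treated"))
#' conditions(cm)
#' @export
CountMatrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (length(condition) != ncol(counts))
    stop("need one condition per sample")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   row.names = colnames(counts)))
  methods::new("CountMatrix", se)
}

#' @describeIn CountMatrix raw count assay.
#' @param object,x a `CountMatrix`.
#' @export
setMethod("counts", "CountMatrix", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' @describeIn CountMatrix per-sample condition labels.
#' @param ... unused.
#' @export
setMethod("conditions", "CountMatrix", function(x, ...)
  SummarizedExperiment::colData(x)$condition)

setMethod("show", "CountMatrix", function(object) {
  cond <- table(conditions(object))
  cat(sprintf("CountMatrix: %d genes x %d samples (%s)\n",
              nrow(object), ncol(object),
              paste(sprintf("%s=%d", names(cond), cond), collapse = ", ")))
})

#' Construct a PathwayCollection
#'
#' @param members named list of character vectors of member gene ids.
#' @param edges named list of two-column character matrices of undirected
#'   edges between members; if omitted, all pathways get empty edge sets.
#' @return A [PathwayCollection-class].
#' @examples
#' pc <- PathwayCollection(list(p1 = c("a", "b", "c")),
#'                         list(p1 = cbind("a", "b")))
#' pathwayNames(pc)
#' @export
PathwayCollection <- function(members, edges = NULL) {
  if (is.null(edges))
    edges <- lapply(members, function(m)
      matrix(character(0), 0, 2))
  ## canonical form: each undirected edge oriented small-id first, rows
  ## sorted and deduplicated, so collections compare with identical()
  edges <- lapply(edges, function(e) {
    e <- as.matrix(e)
    dimnames(e) <- NULL
    if (!nrow(e)) return(matrix(character(0), 0, 2))
    flip <- e[, 1] > e[, 2]
    e[flip, ] <- e[flip, c(2, 1), drop = FALSE]
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    e[!duplicated(paste(e[, 1], e[, 2], sep = "\r")), , drop = FALSE]
  })
  methods::new("PathwayCollection", members = members, edges = edges[names(members)])
}

#' @describeIn PathwayCollection pathway ids.
#' @param x,object a `PathwayCollection`.
#' @export
setMethod("pathwayNames", "PathwayCollection", function(x) names(x@members))

#' @describeIn PathwayCollection member ids of one pathway (or all, as list).
#' @param pathway pathway id; if missing, the full named list.
#' @export
setMethod("members", "PathwayCollection", function(x, pathway) {
  if (missing(pathway)) x@members else x@members[[pathway]]
})

#' @describeIn PathwayCollection edge matrix of one pathway (or all, as list).
#' @export
setMethod("pathwayEdges", "PathwayCollection", function(x, pathway) {
  if (missing(pathway)) x@edges else x@edges[[pathway]]
})

#' @describeIn PathwayCollection number of pathways.
#' @export
setMethod("length", "PathwayCollection", function(x) length(x@members))

setMethod("show", "PathwayCollection", function(object) {
  sz <- lengths(object@members)
  ne <- sum(vapply(object@edges, nrow, 0L))
  cat(sprintf("PathwayCollection: %d pathways, %d distinct genes, %d edges\n",
              length(object), length(unique(unlist(object@members))), ne))
  if (length(object))
    cat(sprintf("  sizes: %d-%d (median %g)\n", min(sz), max(sz),
                stats::median(sz)))
})

#' @describeIn MergedNetwork vertex names of the connected graph.
#' @param x,object a `MergedNetwork`.
#' @export
setMethod("nodeNames", "MergedNetwork", function(x) igraph::V(x@graph)$name)

#' @describeIn MergedNetwork named vector of node degrees.
#' @export
setMethod("degrees", "MergedNetwork", function(x) {
  d <- igraph::degree(x@graph)
  names(d) <- nodeNames(x)
  d
})

#' @describeIn MergedNetwork named character vector of DE status per node.
#' @export
setMethod("deStatus", "MergedNetwork", function(x)
  stats::setNames(x@nodeData$de_status, rownames(x@nodeData)))

#' @describeIn MergedNetwork replace DE status (named or positional).
#' @param value character vector of `"up"`/`"down"`/`"none"`.
#' @export
setMethod("deStatus<-", "MergedNetwork", function(x, value) {
  if (!is.null(names(value))) {
    st <- stats::setNames(rep("none", length(nodeNames(x))), nodeNames(x))
    st[intersect(names(value), names(st))] <-
      value[intersect(names(value), names(st))]
    value <- st
  }
  stopifnot(length(value) == nrow(x@nodeData),
            all(value %in% c("up", "down", "none")))
  x@nodeData$de_status <- unname(value)
  x
})

#' @describeIn MergedNetwork named logical vector of hub flags.
#' @export
setMethod("isHub", "MergedNetwork", function(x) {
  if (!"is_hub" %in% colnames(x@nodeData))
    stop("network not annotated; run annotateTopology() first")
  stats::setNames(x@nodeData$is_hub, rownames(x@nodeData))
})

#' @describeIn MergedNetwork member ids with no incident interaction.
#' @export
setMethod("singletons", "MergedNetwork", function(x) x@singletons)

setMethod("show", "MergedNetwork", function(object) {
  g <- object@graph
  cat(sprintf("MergedNetwork: %d nodes, %d edges, %d singletons (from %d pathways)\n",
              igraph::vcount(g), igraph::ecount(g),
              length(object@singletons), length(object@pathwayIds)))
  if ("is_hub" %in% colnames(object@nodeData))
    cat(sprintf("  %d hubs (degree > %g); DE nodes: %d\n",
                sum(object@nodeData$is_hub), object@hubThreshold,
                sum(object@nodeData$de_status != "none")))
})

#' @describeIn HomologyMap the pair table (`geneA`, `geneB`, `scoreAB`,
#'   `scoreBA`).
#' @param x,object a `HomologyMap`.
#' @export
setMethod("homologPairs", "HomologyMap", function(x) x@pairs)

#' @describeIn HomologyMap number of pairs.
#' @export
setMethod("length", "HomologyMap", function(x) nrow(x@pairs))

setMethod("show", "HomologyMap", function(object) {
  cat(sprintf("HomologyMap: %d one-to-one pairs\n", length(object)))
})

setMethod("show", "NeighborhoodTestResult", function(object) {
  cat("Neighborhood DE-enrichment permutation test\n")
  cat(sprintf("  seeds: %s (radius %d%s)\n",
              paste(object@seeds, collapse = ", "), object@radius,
              if (object@restrictedToHubs) ", hubs only" else ""))
  cat(sprintf("  neighborhood: %d nodes, %d DE observed\n",
              object@neighborhoodSize, object@observedDE))
  if (object@degenerate) {
    cat("  degenerate null (sd = 0); z undefined\n")
  } else {
    cat(sprintf("  null: mean %.3f, sd %.3f over %d permutations\n",
                object@nullMean, object@nullSd, object@nPerm))
    cat(sprintf("  z = %.3f, p_normal = %.4g, p_empirical = %.4g\n",
                object@z, object@pNormal, object@pEmpirical))
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d genes x %d sample(s)/condition, DE fraction %.3g",
    " (|lfc| = %g)\n  %d pathways (size %d-%d, edge density %.2g), seeds: %s\n"),
    object@nGenes, object@nSamplesPerCondition, object@deFraction,
    object@deLfcMagnitude, object@nPathways, object@pathwaySizeRange[1],
    object@pathwaySizeRange[2], object@edgeDensity,
    if (length(object@seedGenes)) paste(object@seedGenes, collapse = ", ")
    else "none"))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(paste0("SyntheticTruth: %d/%d DE in species A, %d/%d in B, ",
                     "%d homolog pairs\n"),
              sum(object@deLabelsA != "none"), length(object@deLabelsA),
              sum(object@deLabelsB != "none"), length(object@deLabelsB),
              nrow(object@homologPairs)))
  if (length(object@seedGenes))
    cat(sprintf("  seeds %s with a planted neighborhood of %d nodes\n",
                paste(object@seedGenes, collapse = ", "),
                length(object@plantedNeighborhood)))
})
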