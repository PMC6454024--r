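## Pathway-network construction: keep every pathway touching at least one DE
## gene, merge their interaction graphs into one simple undirected network,
## and compute degree-based topology (hubs = degree strictly greater than 20,
## neighborhood connectivity = mean neighbor degree). Members that carry no
## interaction anywhere are singletons: reported, but outside the graph and
## all degree statistics.

#' Select pathways containing at least one DE gene
#'
#' @param collection a [PathwayCollection-class].
#' @param deGenes character vector of DE gene ids; a warning is issued when
#'   empty (the selection is then empty too).
#' @return the sub-collection of pathways whose membership intersects
#'   `deGenes`.
#' @export
selectPathways <- function(collection, deGenes) {
  if (!length(deGenes)) warning("empty DE gene set; no pathway selected")
  keep <- vapply(members(collection),
                 function(m) any(m %in% deGenes), logical(1))
  PathwayCollection(members(collection)[keep], pathwayEdges(collection)[keep])
}

#' Merge a pathway collection into one network
#'
#' Union of all member sets as nodes and all intra-pathway edges as an
#' undirected, deduplicated, loop-free edge set. Members without any incident
#' edge become singletons, kept separately from the graph.
#'
#' @param collection a [PathwayCollection-class].
#' @param deGenes optional DE gene ids used to annotate `de_status` on the
#'   nodes (may also be set later via [deStatus<-]). Either a character
#'   vector of DE ids or a named status vector (`"up"`/`"down"`/`"none"`).
#' @return a [MergedNetwork-class] with degrees annotated.
#' @export
mergeNetwork <- function(collection, deGenes = character(0)) {
  allMembers <- unique(unlist(members(collection), use.names = FALSE))
  em <- do.call(rbind, unname(pathwayEdges(collection)))
  if (is.null(em)) em <- matrix(character(0), 0, 2)
  ## canonical orientation, then deduplicate; drop self-loops defensively
  em <- em[em[, 1] != em[, 2], , drop = FALSE]
  flip <- em[, 1] > em[, 2]
  em[flip, ] <- em[flip, c(2, 1), drop = FALSE]
  em <- em[!duplicated(paste(em[, 1], em[, 2], sep = "\r")), , drop = FALSE]
  connected <- sort(unique(c(em)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = connected, stringsAsFactors = FALSE))
  net <- methods::new("MergedNetwork",
    graph = g,
    nodeData = S4Vectors::DataFrame(
      de_status = rep("none", length(connected)),
      degree = as.integer(igraph::degree(g)),
      row.names = connected),
    singletons = sort(setdiff(allMembers, connected)),
    hubThreshold = NA_real_,
    pathwayIds = names(members(collection)) %||% character(0))
  if (length(deGenes)) {
    if (is.null(names(deGenes)))
      deGenes <- stats::setNames(rep("up", length(deGenes)), deGenes)
    deStatus(net) <- deGenes
  }
  net
}

#' Annotate degree, hub status and neighborhood connectivity
#'
#' @param net a [MergedNetwork-class].
#' @param hubThreshold hubs are nodes with degree strictly greater than this
#'   (default 20, so degree 21 is a hub and degree 20 is not).
#' @return the network with `degree`, `is_hub` and
#'   `neighborhood_connectivity` (mean degree of a node's neighbors) filled
#'   in for every node.
#' @export
annotateTopology <- function(net, hubThreshold = 20) {
  g <- net@graph
  deg <- igraph::degree(g)
  nc <- vapply(seq_len(igraph::vcount(g)), function(i) {
    nb <- igraph::neighbors(g, i)
    if (length(nb)) mean(deg[nb]) else NA_real_
  }, numeric(1))
  net@nodeData$degree <- as.integer(deg)
  net@nodeData$is_hub <- deg > hubThreshold
  net@nodeData$neighborhood_connectivity <- nc
  net@hubThreshold <- hubThreshold
  methods::validObject(net)
  net
}

#' Remove a gene module from the network
#'
#' Deletes the listed nodes with their incident edges and recomputes degrees,
#' hub flags and neighborhood connectivity. Nodes isolated by the removal
#' join the singleton set. Useful for excising a self-contained complex (for
#' instance a densely interconnected ribosomal-protein cluster) that would
#' otherwise dominate the degree distribution.
#'
#' @param net an annotated [MergedNetwork-class].
#' @param geneList ids to remove; absent ids trigger a warning, not an error.
#' @return the reduced, re-annotated network.
#' @export
excludeGeneModule <- function(net, geneList) {
  if (!length(geneList)) return(net)
  absent <- setdiff(geneList, c(nodeNames(net), net@singletons))
  if (length(absent))
    warning("not in network: ", paste(absent, collapse = ", "))
  st <- deStatus(net)
  g <- igraph::delete_vertices(net@graph,
                               intersect(geneList, nodeNames(net)))
  isolated <- igraph::V(g)$name[igraph::degree(g) == 0]
  g <- igraph::delete_vertices(g, isolated)
  keep <- igraph::V(g)$name
  net@graph <- g
  net@nodeData <- S4Vectors::DataFrame(
    de_status = unname(st[keep]),
    degree = as.integer(igraph::degree(g)),
    row.names = keep)
  net@singletons <- sort(setdiff(unique(c(net@singletons, isolated)),
                                 geneList))
  thr <- if (is.na(net@hubThreshold)) 20 else net@hubThreshold
  annotateTopology(net, thr)
}

#' Empirical cumulative degree distribution of a node group
#'
#' Right-continuous ECDF of the degrees of DE or non-DE nodes in the
#' connected network (singletons excluded by construction).
#'
#' @param net an annotated [MergedNetwork-class].
#' @param group `"DE"` (any up/down node) or `"nonDE"`.
#' @return list with sorted unique `degree` knots and the `cumfrac` reached
#'   at each knot (non-decreasing, ending at 1).
#' @export
degreeEcdf <- function(net, group = c("DE", "nonDE")) {
  group <- match.arg(group)
  st <- deStatus(net)
  sel <- if (group == "DE") st != "none" else st == "none"
  if (!any(sel)) stop("no ", group, " node in the network")
  d <- sort(unname(degrees(net)[sel]))
  knots <- unique(d)
  list(degree = knots,
       cumfrac = cumsum(tabulate(match(d, knots))) / length(d))
}

#' Node overlap between two species' networks
#'
#' Matches nodes across networks through a homology map (or by identical ids
#' when `map` is omitted) and reports shared node counts, each network's
#' shared percentage (rounded half up to integers), and the number of shared
#' pathway ids.
#'
#' @param netA,netB annotated [MergedNetwork-class] objects.
#' @param map optional [HomologyMap-class] translating A ids to B ids.
#' @param includeSingletons also count singleton members (default FALSE:
#'   overlap of the connected networks).
#' @return list with `sharedNodes`, `percentA`, `percentB`, `sharedPathways`.
#' @export
networkOverlap <- function(netA, netB, map = NULL,
                           includeSingletons = FALSE) {
  nodesA <- nodeNames(netA)
  nodesB <- nodeNames(netB)
  if (includeSingletons) {
    nodesA <- c(nodesA, singletons(netA))
    nodesB <- c(nodesB, singletons(netB))
  }
  if (!is.null(map)) {
    tr <- stats::setNames(homologPairs(map)$geneB, homologPairs(map)$geneA)
    nodesAinB <- unname(tr[nodesA])
    nodesAinB <- nodesAinB[!is.na(nodesAinB)]
  } else {
    nodesAinB <- nodesA
  }
  shared <- length(intersect(nodesAinB, nodesB))
  list(sharedNodes = shared,
       percentA = reportPercent(shared, length(nodesA)),
       percentB = reportPercent(shared, length(nodesB)),
       sharedPathways = length(intersect(netA@pathwayIds, netB@pathwayIds)))
}
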