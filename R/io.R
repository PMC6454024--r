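## Plain-text interchange. Counts travel as TSV with a gene_id column and a
## sidecar condition map; pathway membership as GMT; interactions as SIF
## with the "pp" relation token; similarity hits in the 12-column BLAST
## tabular layout (qseqid sseqid pident length mismatch gapopen qstart qend
## sstart send evalue bitscore -- only columns 1, 2, 4, 7, 8 and 12 are
## consumed, extras ignored); configuration and ground truth as YAML.

.checkIds <- function(ids, what) {
  bad <- grepl("[\t\n]", ids)
  if (any(bad))
    stop(what, " contain tab or newline characters: ",
         paste(utils::head(ids[bad], 3), collapse = ", "))
  invisible(ids)
}

.writeTSV <- function(d, path) {
  ok <- try(utils::write.table(d, path, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write ", path, ": ", attr(ok, "condition")$message)
  invisible(path)
}

#' Write / read a count matrix with its condition map
#'
#' `writeCountMatrix` produces `<prefix>.tsv` (header `gene_id` then sample
#' ids) and `<prefix>_conditions.tsv` (`sample_id`, `condition`);
#' `readCountMatrix` reverses it.
#'
#' @param x a [CountMatrix-class].
#' @param prefix file path prefix (no extension).
#' @return `writeCountMatrix`: the two paths, invisibly; `readCountMatrix`:
#'   a [CountMatrix-class].
#' @export
writeCountMatrix <- function(x, prefix) {
  .checkIds(rownames(x), "gene ids")
  .checkIds(colnames(x), "sample ids")
  d <- data.frame(gene_id = rownames(x), counts(x), check.names = FALSE)
  .writeTSV(d, paste0(prefix, ".tsv"))
  .writeTSV(data.frame(sample_id = colnames(x), condition = conditions(x)),
            paste0(prefix, "_conditions.tsv"))
  invisible(c(paste0(prefix, ".tsv"), paste0(prefix, "_conditions.tsv")))
}

#' @rdname writeCountMatrix
#' @export
readCountMatrix <- function(prefix) {
  d <- utils::read.delim(paste0(prefix, ".tsv"), check.names = FALSE)
  cond <- utils::read.delim(paste0(prefix, "_conditions.tsv"))
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  CountMatrix(m, cond$condition[match(colnames(m), cond$sample_id)])
}

#' Write / read a pathway collection as GMT + SIF
#'
#' The GMT file carries membership (pathway id, description, members; tab
#' separated); the SIF file carries the deduplicated undirected interactions
#' as `nodeA pp nodeB` lines. On reading, each interaction is assigned to
#' every pathway whose membership contains both endpoints (induced-subgraph
#' semantics, as produced by [simulatePathwayCollection()]).
#'
#' @param x a [PathwayCollection-class].
#' @param gmt,sif file paths.
#' @return `writePathwayCollection`: the paths, invisibly;
#'   `readPathwayCollection`: a [PathwayCollection-class].
#' @export
writePathwayCollection <- function(x, gmt, sif) {
  .checkIds(unlist(members(x), use.names = FALSE), "gene ids")
  .checkIds(pathwayNames(x), "pathway ids")
  lines <- vapply(pathwayNames(x), function(p)
    paste(c(p, "na", members(x, p)), collapse = "\t"), character(1))
  writeLines(unname(lines), gmt)
  allE <- do.call(rbind, c(list(matrix(character(0), 0, 2)),
                           unname(pathwayEdges(x))))
  if (nrow(allE)) {
    flip <- allE[, 1] > allE[, 2]
    allE[flip, ] <- allE[flip, c(2, 1), drop = FALSE]
    allE <- allE[!duplicated(paste(allE[, 1], allE[, 2], sep = "\r")), ,
                 drop = FALSE]
    allE <- allE[order(allE[, 1], allE[, 2]), , drop = FALSE]
  }
  writeLines(if (nrow(allE)) paste(allE[, 1], "pp", allE[, 2]) else
             character(0), sif)
  invisible(c(gmt, sif))
}

#' @rdname writePathwayCollection
#' @export
readPathwayCollection <- function(gmt, sif) {
  glines <- readLines(gmt)
  membs <- list()
  for (l in glines) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    membs[[f[1]]] <- f[-(1:2)]
  }
  slines <- readLines(sif)
  em <- if (length(slines)) {
    f <- do.call(rbind, strsplit(trimws(slines), "[ \t]+"))
    if (ncol(f) != 3 || !all(f[, 2] == "pp"))
      stop("malformed SIF file: expected 'nodeA pp nodeB' lines")
    f[, c(1, 3), drop = FALSE]
  } else matrix(character(0), 0, 2)
  edges <- lapply(membs, function(m)
    em[em[, 1] %in% m & em[, 2] %in% m, , drop = FALSE])
  PathwayCollection(membs, edges)
}

#' Write / read a hit table in BLAST tabular layout
#'
#' Writes the standard 12 columns; percent identity, mismatches, gap opens,
#' subject coordinates and e-value are synthesized placeholders, while
#' `qstart = 1`, `qend = query length` preserve the query length for the
#' reciprocal-best-hit tie-break. The reader accepts any file with at least
#' 12 tab-separated columns and ignores extras.
#'
#' @param hits a hit table ([hitTable()]).
#' @param path file path.
#' @return `writeHitTable`: the path, invisibly; `readHitTable`: a hit table.
#' @export
writeHitTable <- function(hits, path) {
  .checkIds(c(hits$query, hits$subject), "sequence ids")
  d <- data.frame(hits$query, hits$subject, 90.0, hits$length, 0L, 0L,
                  1L, hits$qlen, 1L, hits$length, 1e-20, hits$bitscore)
  ok <- try(utils::write.table(d, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write ", path, ": ", attr(ok, "condition")$message)
  invisible(path)
}

#' @rdname writeHitTable
#' @export
readHitTable <- function(path) {
  d <- utils::read.delim(path, header = FALSE)
  if (ncol(d) < 12) stop("expected >= 12 tabular columns in ", path)
  hitTable(d[[1]], d[[2]], d[[12]], d[[4]], qlen = d[[8]] - d[[7]] + 1L)
}

## SimulationConfig <-> plain list (for YAML)
.configToList <- function(config) {
  sl <- methods::slotNames("SimulationConfig")
  stats::setNames(lapply(sl, function(s) methods::slot(config, s)), sl)
}

.configFromList <- function(x) {
  do.call(simulationConfig, lapply(x, unlist))
}

.truthToList <- function(truth) {
  list(deLabelsA = as.list(truth@deLabelsA),
       deLabelsB = as.list(truth@deLabelsB),
       homologA = truth@homologPairs$geneA,
       homologB = truth@homologPairs$geneB,
       plantedNeighborhood = truth@plantedNeighborhood,
       seedGenes = truth@seedGenes)
}

.truthFromList <- function(x) {
  methods::new("SyntheticTruth",
    deLabelsA = unlist(x$deLabelsA) %||% stats::setNames(character(0), NULL),
    deLabelsB = unlist(x$deLabelsB) %||% stats::setNames(character(0), NULL),
    homologPairs = data.frame(geneA = as.character(unlist(x$homologA)),
                              geneB = as.character(unlist(x$homologB)),
                              stringsAsFactors = FALSE),
    plantedNeighborhood = as.character(unlist(x$plantedNeighborhood)),
    seedGenes = as.character(unlist(x$seedGenes)))
}

#' Write / read a complete synthetic dataset
#'
#' Persists every component of a [simulateDataset()] result in the
#' pipeline's input formats: counts + condition maps as TSV, pathways as
#' GMT + SIF per species, hit tables as BLAST tabular, and configuration +
#' ground truth as YAML. `readDataset` round-trips the directory back into
#' an equal in-memory dataset.
#'
#' @param dataset list from [simulateDataset()].
#' @param dir output directory (created if missing).
#' @return `writeDataset`: `dir`, invisibly; `readDataset`: the dataset list.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  writeCountMatrix(dataset$countsA, file.path(dir, "counts_a"))
  writeCountMatrix(dataset$countsB, file.path(dir, "counts_b"))
  writePathwayCollection(dataset$pathwaysA, file.path(dir, "pathways_a.gmt"),
                         file.path(dir, "pathways_a.sif"))
  writePathwayCollection(dataset$pathwaysB, file.path(dir, "pathways_b.gmt"),
                         file.path(dir, "pathways_b.sif"))
  writeHitTable(dataset$hitsAB, file.path(dir, "hits_ab.tsv"))
  writeHitTable(dataset$hitsBA, file.path(dir, "hits_ba.tsv"))
  yaml::write_yaml(.truthToList(dataset$truth), file.path(dir, "truth.yaml"))
  yaml::write_yaml(.configToList(dataset$config),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  list(countsA = readCountMatrix(file.path(dir, "counts_a")),
       countsB = readCountMatrix(file.path(dir, "counts_b")),
       pathwaysA = readPathwayCollection(file.path(dir, "pathways_a.gmt"),
                                         file.path(dir, "pathways_a.sif")),
       pathwaysB = readPathwayCollection(file.path(dir, "pathways_b.gmt"),
                                         file.path(dir, "pathways_b.sif")),
       hitsAB = readHitTable(file.path(dir, "hits_ab.tsv")),
       hitsBA = readHitTable(file.path(dir, "hits_ba.tsv")),
       truth = .truthFromList(yaml::read_yaml(file.path(dir, "truth.yaml"))),
       config = .configFromList(yaml::read_yaml(file.path(dir,
                                                          "config.yaml"))))
}

#' Write a merged network as SIF plus a node-attribute table
#'
#' @param net an annotated [MergedNetwork-class].
#' @param sif path for the edge list (`nodeA pp nodeB`).
#' @param attrs path for the node table (`node`, `de_status`, `degree`,
#'   `is_hub`, `neighborhood_connectivity`; singletons included with degree
#'   0).
#' @return the paths, invisibly.
#' @export
writeNetwork <- function(net, sif, attrs) {
  em <- igraph::as_edgelist(net@graph)
  if (nrow(em)) {
    flip <- em[, 1] > em[, 2]
    em[flip, ] <- em[flip, c(2, 1), drop = FALSE]
    em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  }
  writeLines(if (nrow(em)) paste(em[, 1], "pp", em[, 2]) else character(0),
             sif)
  nd <- as.data.frame(net@nodeData)
  d <- data.frame(node = rownames(nd), nd, row.names = NULL)
  if (length(singletons(net)))
    d <- rbind(d, data.frame(node = singletons(net), de_status = "none",
                             degree = 0L, is_hub = FALSE,
                             neighborhood_connectivity = NA_real_))
  .writeTSV(d, attrs)
  invisible(c(sif, attrs))
}
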