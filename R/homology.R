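## Reciprocal-best-hit homology from similarity search tables. Hits are
## gene-level: multiple local alignments per (query, subject) pair collapse
## to the best bit-score before any comparison. Deterministic tie-breaking:
## score desc, then longer query, then lexicographically smaller id.

#' Construct a hit table
#'
#' @param query,subject gene ids.
#' @param bitscore non-negative alignment bit-scores.
#' @param length alignment lengths.
#' @param qlen query sequence lengths; defaults to the alignment length when
#'   the source format does not carry them.
#' @return data.frame of class `HitTable` with those five columns.
#' @export
hitTable <- function(query, subject, bitscore, length, qlen = length) {
  stopifnot(all(bitscore >= 0))
  d <- data.frame(query = as.character(query),
                  subject = as.character(subject),
                  bitscore = as.numeric(bitscore),
                  length = as.integer(length),
                  qlen = as.integer(qlen),
                  stringsAsFactors = FALSE)
  class(d) <- c("HitTable", "data.frame")
  d
}

#' Drop weak hits
#'
#' Removes rows with bit-score strictly below `minBitscore`; the default 100
#' keeps a hit scoring exactly 100 and drops one scoring 99.
#'
#' @param hits a hit table (see [hitTable()]).
#' @param minBitscore strict lower bound on retained bit-scores.
#' @return the filtered hit table.
#' @export
filterHits <- function(hits, minBitscore = 100) {
  hits[hits$bitscore >= minBitscore, , drop = FALSE]
}

## order rows so the preferred assignment per group comes first:
## highest score, then longest query, then smallest id
.hitOrder <- function(hits, idCol) {
  order(-hits$bitscore, -hits$qlen, hits[[idCol]])
}

## collapse HSP-level rows to one row per (query, subject), keeping max score
.collapseHSP <- function(hits) {
  if (!nrow(hits)) return(hits)
  key <- paste(hits$query, hits$subject, sep = "\r")
  hits <- hits[order(key, -hits$bitscore), , drop = FALSE]
  hits[!duplicated(paste(hits$query, hits$subject, sep = "\r")), , drop = FALSE]
}

#' Deduplicate assignments sharing a subject
#'
#' When several queries are assigned to the same subject, keeps per subject
#' the assignment with the highest bit-score; among equal scores the longest
#' query; among equal lengths the lexicographically smallest query id.
#'
#' @param hits a hit table of assignments.
#' @return hit table with one row per subject.
#' @export
collapseDuplicates <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[.hitOrder(hits, "query"), , drop = FALSE]
  hits[!duplicated(hits$subject), , drop = FALSE]
}

## best subject per query under the same tie-break (score, qlen, subject id)
.bestPerQuery <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$query, -hits$bitscore, hits$subject), , drop = FALSE]
  hits[!duplicated(hits$query), , drop = FALSE]
}

#' Best reciprocal hits
#'
#' Builds the one-to-one homology map: a pair (a, b) is kept iff b is a's
#' top-scoring subject in the A-to-B table and a is b's top-scoring subject
#' in the B-to-A table. Both tables should already be bit-score filtered
#' ([filterHits()]); multiple alignments per gene pair are collapsed to their
#' best score first. Queries assigned to an already-claimed subject are
#' resolved by [collapseDuplicates()] before the reciprocal check, so the
#' result is one-to-one by construction.
#'
#' @param hitsAB hit table with species-A queries and species-B subjects.
#' @param hitsBA hit table with species-B queries and species-A subjects.
#' @return a [HomologyMap-class].
#' @export
bestReciprocalHits <- function(hitsAB, hitsBA) {
  ab <- collapseDuplicates(.bestPerQuery(.collapseHSP(hitsAB)))
  ba <- collapseDuplicates(.bestPerQuery(.collapseHSP(hitsBA)))
  if (!nrow(ab) || !nrow(ba)) {
    return(methods::new("HomologyMap", pairs = data.frame(
      geneA = character(0), geneB = character(0),
      scoreAB = numeric(0), scoreBA = numeric(0))))
  }
  bestB <- stats::setNames(ab$subject, ab$query)      # a -> its best b
  bestA <- stats::setNames(ba$subject, ba$query)      # b -> its best a
  a <- ab$query
  b <- bestB[a]
  mutual <- !is.na(bestA[b]) & bestA[b] == a
  pairs <- data.frame(
    geneA = unname(a[mutual]),
    geneB = unname(b[mutual]),
    scoreAB = ab$bitscore[mutual],
    scoreBA = unname(stats::setNames(ba$bitscore, ba$query)[b[mutual]]),
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$geneA), , drop = FALSE]
  rownames(pairs) <- NULL
  methods::new("HomologyMap", pairs = pairs)
}

#' Cross-species comparison of DE calls over homolog pairs
#'
#' For every mapped pair, looks up the DE status of each member in its
#' species' expression table and classifies pairs DE in both species by sign
#' agreement; pairs DE in exactly one species are counted as species-specific.
#'
#' @param map a [HomologyMap-class].
#' @param tableA,tableB expression tables (see [expressionTable()]) covering
#'   the mapped genes of species A and B.
#' @return list with data.frame `pairs` (per mapped pair: statuses and class)
#'   and integer `counts` (`shared_de`, `concordant_up`, `concordant_down`,
#'   `opposite`, `a_specific`, `b_specific`).
#' @export
compareDESets <- function(map, tableA, tableB) {
  p <- homologPairs(map)
  stA <- stats::setNames(tableA$de_status, tableA$gene_id)
  stB <- stats::setNames(tableB$de_status, tableB$gene_id)
  missA <- setdiff(p$geneA, names(stA))
  missB <- setdiff(p$geneB, names(stB))
  if (length(missA) || length(missB))
    stop("mapped genes missing from expression tables: ",
         paste(c(missA, missB), collapse = ", "))
  a <- unname(stA[p$geneA])
  b <- unname(stB[p$geneB])
  cls <- rep("neither", nrow(p))
  cls[a != "none" & b == "none"] <- "a_specific"
  cls[a == "none" & b != "none"] <- "b_specific"
  both <- a != "none" & b != "none"
  cls[both & a == b & a == "up"] <- "concordant_up"
  cls[both & a == b & a == "down"] <- "concordant_down"
  cls[both & a != b] <- "opposite"
  pairs <- data.frame(p[, c("geneA", "geneB")], statusA = a, statusB = b,
                      class = cls, stringsAsFactors = FALSE)
  counts <- c(
    concordant_up = sum(cls == "concordant_up"),
    concordant_down = sum(cls == "concordant_down"),
    opposite = sum(cls == "opposite"),
    a_specific = sum(cls == "a_specific"),
    b_specific = sum(cls == "b_specific"))
  counts <- c(shared_de = unname(counts["concordant_up"] +
                counts["concordant_down"] + counts["opposite"]), counts)
  list(pairs = pairs, counts = counts)
}
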