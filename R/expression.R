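## Differential expression for a no-replicate treated-vs-control contrast:
## discard weakly covered genes, equalize depth with median-of-ratios size
## factors, and call DE on a pseudocount-stabilized log2 fold change with an
## inclusive +/- threshold. There is no replicate-based significance test by
## design; the threshold IS the call.

#' Discard genes with low total counts
#'
#' Removes genes whose raw count summed over all samples is strictly below
#' `minTotal` (default 50, i.e. totals of 49 go, totals of 50 stay). Order of
#' the surviving genes is preserved.
#'
#' @param x a [CountMatrix-class].
#' @param minTotal integer; genes with total < `minTotal` are dropped.
#' @return the filtered `CountMatrix`.
#' @export
filterLowCounts <- function(x, minTotal = 50) {
  stopifnot(methods::is(x, "CountMatrix"))
  keep <- rowSums(counts(x)) >= minTotal
  if (!any(keep))
    warning("all genes fall below the low-count threshold")
  x[keep, ]
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over reference genes of the ratio between that
#' sample's count and the gene's geometric mean across samples. Reference
#' genes are those with strictly positive counts in every sample, so the
#' geometric mean is finite and nonzero.
#'
#' @param x a [CountMatrix-class].
#' @return named numeric vector of positive per-sample factors.
#' @export
estimateSizeFactors <- function(x) {
  stopifnot(methods::is(x, "CountMatrix"))
  m <- counts(x)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("no gene has positive counts in every sample; ",
         "size factors are undefined")
  mr <- m[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(mr)))
  sf <- apply(mr, 2, function(col) stats::median(col / geo))
  stats::setNames(sf, colnames(m))
}

## counts scaled to common depth: count / size factor
normalizeCounts <- function(x, sizeFactors = estimateSizeFactors(x)) {
  sweep(counts(x), 2, sizeFactors[colnames(x)], "/")
}

#' Pseudocount-stabilized log2 fold change (treated vs control)
#'
#' `log2((mean normalized treated + pseudocount) /
#' (mean normalized control + pseudocount))`, computed per gene. The
#' pseudocount keeps the ratio finite for genes with zero counts in one
#' condition; direction is treated over control throughout.
#'
#' @param x a [CountMatrix-class] with both conditions present.
#' @param sizeFactors per-sample factors from [estimateSizeFactors()].
#' @param pseudocount added to both normalized condition means (default 1).
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
log2FoldChange <- function(x, sizeFactors = estimateSizeFactors(x),
                           pseudocount = 1) {
  stopifnot(methods::is(x, "CountMatrix"))
  cond <- conditions(x)
  if (!all(c("control", "treated") %in% cond))
    stop("need both control and treated samples")
  nm <- normalizeCounts(x, sizeFactors)
  mc <- rowMeans(nm[, cond == "control", drop = FALSE])
  mt <- rowMeans(nm[, cond == "treated", drop = FALSE])
  stats::setNames(log2((mt + pseudocount) / (mc + pseudocount)), rownames(x))
}

#' Call differential expression from fold changes
#'
#' Inclusive threshold rule: `up` when lfc >= threshold, `down` when
#' lfc <= -threshold, `none` otherwise. A gene at exactly +1 (or -1) under
#' the default threshold is called.
#'
#' @param lfc named numeric vector of log2 fold changes.
#' @param threshold positive threshold (default 1).
#' @return named character vector with values `"up"`, `"down"`, `"none"`.
#' @export
callDE <- function(lfc, threshold = 1) {
  bad <- !is.finite(lfc)
  if (any(bad))
    stop("non-finite log2 fold change for: ",
         paste(names(lfc)[bad] %||% which(bad), collapse = ", "))
  status <- rep("none", length(lfc))
  status[lfc >= threshold] <- "up"
  status[lfc <= -threshold] <- "down"
  stats::setNames(status, names(lfc))
}

#' Full DE table for one species
#'
#' Runs the fixed pipeline filter -> size factors -> fold change -> call and
#' returns one row per surviving gene. Idempotent on already-filtered input.
#'
#' @param x a [CountMatrix-class].
#' @param minTotal low-count filter threshold (see [filterLowCounts()]).
#' @param lfcThreshold DE call threshold (see [callDE()]).
#' @param pseudocount see [log2FoldChange()].
#' @return data.frame with columns `gene_id`, `total_count`,
#'   `norm_mean_control`, `norm_mean_treated`, `log2fc`, `de_status`.
#' @examples
#' cm <- CountMatrix(matrix(c(100L, 10L, 400L, 10L), 2, 2,
#'                   dimnames = list(c("g1", "g2"), c("c", "t"))),
#'                   c("control", "treated"))
#' expressionTable(cm, minTotal = 10)
#' @export
expressionTable <- function(x, minTotal = 50, lfcThreshold = 1,
                            pseudocount = 1) {
  x <- filterLowCounts(x, minTotal)
  sf <- estimateSizeFactors(x)
  nm <- normalizeCounts(x, sf)
  cond <- conditions(x)
  lfc <- log2FoldChange(x, sf, pseudocount)
  data.frame(
    gene_id = rownames(x),
    total_count = unname(rowSums(counts(x))),
    norm_mean_control = unname(rowMeans(nm[, cond == "control", drop = FALSE])),
    norm_mean_treated = unname(rowMeans(nm[, cond == "treated", drop = FALSE])),
    log2fc = unname(lfc),
    de_status = unname(callDE(lfc, lfcThreshold)),
    stringsAsFactors = FALSE)
}

#' PCA quality control of log-normalized counts
#'
#' Principal component analysis of samples on `log2(normalized count + 1)`,
#' with genes centered, to check that the leading components track the
#' biology (condition, species) rather than technical noise.
#'
#' @param x a [CountMatrix-class] with at least two samples.
#' @return list with `varianceFraction` (per component, summing to 1) and
#'   `coordinates` (samples x components score matrix).
#' @export
qcPCA <- function(x) {
  stopifnot(methods::is(x, "CountMatrix"))
  if (ncol(x) < 2) stop("PCA needs at least 2 samples")
  lm <- t(log2(normalizeCounts(x) + 1))
  pc <- stats::prcomp(lm, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  list(varianceFraction = v / sum(v), coordinates = pc$x)
}
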