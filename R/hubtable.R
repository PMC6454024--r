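#' Published hub table of the axolotl / X. tropicalis contrast
#'
#' The non-ribosomal rows of the published list of differentially expressed
#' hubs in the axolotl vs *Xenopus tropicalis* tailfin comparison: per gene,
#' both species' log2 fold changes, the node degree, and the neighborhood
#' connectivity in the merged pathway network. Shipped as a worked example
#' for the DE-call partition rule.
#'
#' @return data.frame with columns `gene`, `log2fc_a` (axolotl), `log2fc_b`
#'   (X. tropicalis), `degree`, `neighborhood_connectivity`.
#' @examples
#' classifyHubRows(publishedHubTable())
#' @export
publishedHubTable <- function() {
  utils::read.delim(system.file("extdata", "table1_hubs.tsv",
                                package = "netcontrast"))
}

#' Partition hub rows by where the DE call fires
#'
#' Applies the inclusive |log2FC| >= threshold call ([callDE()]) to both
#' species' fold-change columns and partitions each row into `a_specific`,
#' `both` or `b_specific`; rows DE in neither species are labeled
#' `neither`. For rows in `both`, sign agreement is reported.
#'
#' @param tbl data.frame with columns `gene`, `log2fc_a`, `log2fc_b`.
#' @param threshold DE threshold (default 1).
#' @return the table with added columns `status_a`, `status_b`, `partition`,
#'   `agreement` (`concordant` / `opposite` / `NA`).
#' @export
classifyHubRows <- function(tbl, threshold = 1) {
  sa <- callDE(stats::setNames(tbl$log2fc_a, tbl$gene), threshold)
  sb <- callDE(stats::setNames(tbl$log2fc_b, tbl$gene), threshold)
  part <- ifelse(sa != "none" & sb != "none", "both",
          ifelse(sa != "none", "a_specific",
          ifelse(sb != "none", "b_specific", "neither")))
  agree <- ifelse(part == "both",
                  ifelse(sa == sb, "concordant", "opposite"), NA)
  cbind(tbl, status_a = unname(sa), status_b = unname(sb),
        partition = unname(part), agreement = unname(agree))
}
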