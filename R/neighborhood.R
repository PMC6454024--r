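## Label-permutation test for DE enrichment around seed nodes: count DE
## nodes among the first- and second-order neighbors of the seeds, rebuild
## the count under random reassignments of the DE labels (same number of DE
## nodes, uniform over the network), and standardize the observed count
## against the permutation null. The null is hypergeometric in the limit;
## the permutation machinery is kept because it generalizes to restricted
## label universes (e.g. hubs only).

#' Nodes within a given radius of the seeds
#'
#' Union over seeds of all nodes at graph distance 1..`radius`; the seeds
#' themselves are excluded (they are DE by construction in the intended use
#' and would bias the enrichment count).
#'
#' @param net a [MergedNetwork-class].
#' @param seeds node ids present in the network.
#' @param radius maximum graph distance (default 2: first and second
#'   neighbors); radius 0 gives an empty set.
#' @return character vector of neighborhood node ids, sorted.
#' @export
extractNeighborhood <- function(net, seeds, radius = 2) {
  absent <- setdiff(seeds, nodeNames(net))
  if (length(absent))
    stop("seed(s) not in network: ", paste(absent, collapse = ", "))
  if (radius <= 0) return(character(0))
  nb <- igraph::ego(net@graph, order = radius, nodes = seeds)
  sort(setdiff(unique(unlist(lapply(nb, function(v) v$name))), seeds))
}

#' Permutation null for the neighborhood DE count
#'
#' Each permutation plants `nDE` DE labels on a uniform random subset of
#' `allNodes` and counts how many land in `neighborhood`. Returns the sample
#' mean and standard deviation (n-1 denominator) of the counts.
#'
#' @param allNodes label universe (character vector or its size as integer).
#' @param nDE number of DE labels to place (0 <= nDE <= |allNodes|).
#' @param neighborhood node ids (subset of `allNodes`) or their count.
#' @param nPerm number of permutations (>= 2).
#' @param rngSeed integer seed.
#' @param returnSamples also return the per-permutation counts.
#' @return list with `nullMean`, `nullSd` and (optionally) `samples`.
#' @export
shuffleNull <- function(allNodes, nDE, neighborhood, nPerm = 1000,
                        rngSeed = 1, returnSamples = FALSE) {
  if (nPerm < 2) stop("nPerm must be at least 2")
  N <- if (is.character(allNodes)) length(allNodes) else as.integer(allNodes)
  if (is.character(neighborhood)) {
    if (is.character(allNodes) && !all(neighborhood %in% allNodes))
      stop("neighborhood must be a subset of the label universe")
    n <- length(neighborhood)
  } else n <- as.integer(neighborhood)
  if (nDE > N) stop("more DE labels than nodes")
  samples <- withSeed(rngSeed, {
    vapply(seq_len(nPerm),
           function(i) sum(sample.int(N, nDE) <= n), integer(1))
  })
  res <- list(nullMean = mean(samples), nullSd = stats::sd(samples))
  if (returnSamples) res$samples <- samples
  res
}

#' Standardize an observed count against the permutation null
#'
#' @param observed observed DE count in the neighborhood.
#' @param nullMean,nullSd permutation null moments from [shuffleNull()].
#' @return list with `z`, two-sided normal `pNormal`
#'   (`2 * (1 - pnorm(|z|))`), and a `degenerate` flag; when `nullSd` is 0
#'   the result is flagged degenerate with `z` and `pNormal` set to `NA`
#'   rather than silently returning NaN.
#' @examples
#' permutationZscore(10, 6, 1.97)
#' @export
permutationZscore <- function(observed, nullMean, nullSd) {
  if (nullSd < 0) stop("nullSd must be non-negative")
  if (nullSd == 0)
    return(list(z = NA_real_, pNormal = NA_real_, degenerate = TRUE))
  z <- (observed - nullMean) / nullSd
  list(z = z, pNormal = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Neighborhood DE-enrichment test
#'
#' Composes [extractNeighborhood()], the observed DE count, [shuffleNull()]
#' and [permutationZscore()]. With `restrictToHubs = TRUE` both the observed
#' count and the label universe are restricted to hub nodes (labels are
#' shuffled among hubs only), matching the "concentration of DE hubs"
#' reading of the statistic; the default counts all DE genes. Alongside the
#' normal-tail p, an empirical two-sided p is reported:
#' `2 * (1 + #\{null >= observed\}) / (nPerm + 1)` capped at 1 (add-one
#' correction, upper tail doubled).
#'
#' @param net an annotated [MergedNetwork-class] with DE status set.
#' @param seeds seed node ids.
#' @param radius neighborhood radius (default 2).
#' @param nPerm number of label permutations (default 1000).
#' @param rngSeed integer seed for the permutations.
#' @param restrictToHubs restrict statistic and shuffling to hubs.
#' @return a [NeighborhoodTestResult-class].
#' @export
neighborhoodDETest <- function(net, seeds, radius = 2, nPerm = 1000,
                               rngSeed = 1, restrictToHubs = FALSE) {
  nbhd <- extractNeighborhood(net, seeds, radius)
  st <- deStatus(net)
  universe <- nodeNames(net)
  if (restrictToHubs) {
    hubs <- names(which(isHub(net)))
    universe <- hubs
    nbhd <- intersect(nbhd, hubs)
  }
  nDE <- sum(st[universe] != "none")
  observed <- sum(st[nbhd] != "none")
  null <- shuffleNull(universe, nDE, nbhd, nPerm = nPerm, rngSeed = rngSeed,
                      returnSamples = TRUE)
  zs <- permutationZscore(observed, null$nullMean, null$nullSd)
  pEmp <- min(1, 2 * (1 + sum(null$samples >= observed)) / (nPerm + 1))
  methods::new("NeighborhoodTestResult",
    seeds = as.character(seeds), radius = as.integer(radius),
    neighborhoodSize = length(nbhd), observedDE = as.integer(observed),
    nullMean = null$nullMean, nullSd = null$nullSd,
    z = zs$z, pNormal = zs$pNormal, pEmpirical = pEmp,
    nPerm = as.integer(nPerm), rngSeed = as.integer(rngSeed),
    restrictedToHubs = restrictToHubs, degenerate = zs$degenerate)
}
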