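#' Node degrees of an interaction network
#'
#' @param net an undirected `igraph` network (see [loadNetwork()]).
#' @return named integer vector, gene -> neighbor count.
#' @export
degreeMap <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  d <- igraph::degree(net, loops = FALSE)
  setNames(as.integer(d), names(d))
}

#' Betweenness centrality of every gene
#'
#' Unnormalized shortest-path betweenness over unordered node pairs with
#' endpoints excluded: for each pair (s, t) a node i accrues the fraction
#' of s-t shortest paths passing through it; disconnected pairs contribute
#' nothing.
#'
#' @param net an undirected `igraph` network.
#' @return named numeric vector, gene -> betweenness.
#' @export
betweennessMap <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  igraph::betweenness(net, directed = FALSE, normalized = FALSE)
}

#' Compare seed-gene centrality with random-set nulls
#'
#' Draws `nPerm` gene sets of the same size as the seed set (without
#' replacement, from all network genes), and compares the observed mean
#' centrality of the seeds with the null means: `fold` is
#' observed / mean(null), and the one-sided empirical p-value for
#' "observed at least as large" uses the +1 correction.
#'
#' @param profile named numeric vector of a centrality (from
#'   [degreeMap()] or [betweennessMap()]).
#' @param seedGenes character vector of seed gene symbols.
#' @param nPerm number of random sets (default 999).
#' @param seed RNG seed.
#' @param metric label stored in the result (e.g. `"degree"`).
#' @return list with `metric`, `observed_mean`, `null_mean`, `fold`,
#'   `p_empirical`, `n_perm`, `n_seed_in_network`, `seed`.
#' @export
randomSetNullComparison <- function(profile, seedGenes, nPerm = 999,
                                    seed = 1, metric = "centrality") {
  inNet <- intersect(.normSymbol(seedGenes), names(profile))
  if (length(inNet) < 2)
    stop("fewer than 2 seed genes present in the network")
  observed <- mean(profile[inNet])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nullMeans <- vapply(seq_len(nPerm), function(i)
    mean(profile[sample(names(profile), length(inNet))]), 0)
  list(metric = metric,
       observed_mean = observed,
       null_mean = mean(nullMeans),
       fold = observed / mean(nullMeans),
       p_empirical = (sum(nullMeans >= observed) + 1) / (nPerm + 1),
       n_perm = nPerm,
       n_seed_in_network = length(inNet),
       seed = seed)
}

#' Keep genes in the top fraction of both centralities
#'
#' A gene passes when its degree is at least the value of the
#' `ceiling(qDegree * n)`-th largest network degree AND its betweenness is
#' at least the corresponding betweenness cut (nearest-rank on the full
#' network distributions; ties at the cut are included). Genes absent from
#' the network never pass. `q = 1` admits every network gene.
#'
#' @param degrees named vector from [degreeMap()].
#' @param betweenness named vector from [betweennessMap()].
#' @param genes character vector of genes to filter (default: all network
#'   genes).
#' @param qDegree,qBetweenness top fractions in (0, 1\].
#' @return sorted character vector of surviving genes.
#' @export
topFractionFilter <- function(degrees, betweenness, genes = names(degrees),
                              qDegree = 0.01, qBetweenness = 0.01) {
  if (qDegree <= 0 || qDegree > 1 || qBetweenness <= 0 || qBetweenness > 1)
    stop("top fractions must lie in (0, 1]")
  genes <- intersect(.normSymbol(genes), names(degrees))
  cutD <- .topFractionCut(degrees, qDegree)
  cutB <- .topFractionCut(betweenness, qBetweenness)
  pass <- degrees[genes] >= cutD & betweenness[genes] >= cutB
  sort(genes[pass])
}
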