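#' Enrichment configuration
#'
#' @param minReadsSpeciesA Minimum species-A read count for a transcript to
#'   be considered expressed (default 8).
#' @param maxReadsSpeciesB Maximum tolerated read count in EACH species-B
#'   dataset (default 0: the transcript must be absent from every
#'   replicate).
#' @param anyDataset If `TRUE`, the species-B bound is required in at least
#'   one dataset instead of each (a laxer reading; default `FALSE`).
#' @param tissueGrouping Named character vector tissue -> group; the default
#'   merges ovary and testis into "gonad".
#' @return A list of class `EnrichmentConfig`.
#' @export
enrichmentConfig <- function(minReadsSpeciesA = 8, maxReadsSpeciesB = 0,
                             anyDataset = FALSE,
                             tissueGrouping = c(brain = "brain",
                                                liver = "liver",
                                                ovary = "gonad",
                                                testis = "gonad")) {
  checkScalarNumber(minReadsSpeciesA, "minReadsSpeciesA", 1)
  checkScalarNumber(maxReadsSpeciesB, "maxReadsSpeciesB", 0)
  structure(list(minReadsSpeciesA = minReadsSpeciesA,
                 maxReadsSpeciesB = maxReadsSpeciesB,
                 anyDataset = isTRUE(anyDataset),
                 tissueGrouping = tissueGrouping),
            class = "EnrichmentConfig")
}

#' Merge per-sample annotated gene sets into per-tissue-group unions
#'
#' Samples of the same tissue group (e.g. the two sexes of one tissue, or
#' ovary and testis merged into gonad) contribute the union of their
#' annotated genes.
#'
#' @param sampleSets Named list of character vectors (annotated gene ids per
#'   sample).
#' @param tissues Character vector, one tissue label per sample.
#' @param config An [enrichmentConfig()]; supplies the tissue -> group map.
#' @return Named list of gene sets, one per tissue group.
#' @export
tissueUnion <- function(sampleSets, tissues, config = enrichmentConfig()) {
  if (length(sampleSets) != length(tissues)) {
    stop("one tissue label per sample set is required")
  }
  unknown <- setdiff(tissues, names(config$tissueGrouping))
  if (length(unknown)) {
    stop(sprintf("unknown tissue label '%s'", unknown[1L]))
  }
  groups <- unname(config$tissueGrouping[tissues])
  out <- lapply(split(sampleSets, groups), function(sets) {
    sort(unique(unlist(sets, use.names = FALSE)))
  })
  out[unique(groups)]
}

#' Tissue-enriched and shared gene sets
#'
#' A gene is enriched in a group when it is annotated in that group and in
#' no other; the shared set is the intersection of all groups.
#'
#' @param groupSets Named list of >= 2 gene sets (one per tissue group).
#' @return List with `enriched` (named list, one set per group), `shared`
#'   (character), and `counts` (data.frame of set sizes).
#' @export
tissueEnriched <- function(groupSets) {
  if (length(groupSets) < 2L) stop("at least two groups are required")
  enriched <- lapply(seq_along(groupSets), function(i) {
    setdiff(groupSets[[i]], unlist(groupSets[-i], use.names = FALSE))
  })
  names(enriched) <- names(groupSets)
  shared <- Reduce(intersect, groupSets)
  counts <- data.frame(group = names(groupSets),
                       annotated = lengths(groupSets),
                       enriched = lengths(enriched))
  list(enriched = enriched, shared = shared, counts = counts)
}

speciesCountsVector <- function(x) {
  if (is(x, "TxCounts")) rowSums(counts(x)) else x
}

#' Species-enriched transcript discovery by read-count filter
#'
#' A transcript is species-A-enriched when it has at least
#' `minReadsSpeciesA` reads in the species-A data and no more than
#' `maxReadsSpeciesB` reads in each of two independent species-B datasets
#' (at most one dataset under `anyDataset = TRUE`).
#'
#' @param countsA Named numeric vector (or [TxCounts-class]) of species-A
#'   read counts.
#' @param countsB1,countsB2 Counts of the two independent species-B
#'   datasets over the same transcript universe.
#' @param config An [enrichmentConfig()].
#' @return Character vector of enriched transcript ids (sorted).
#' @export
speciesEnriched <- function(countsA, countsB1, countsB2,
                            config = enrichmentConfig()) {
  a <- speciesCountsVector(countsA)
  b1 <- speciesCountsVector(countsB1)
  b2 <- speciesCountsVector(countsB2)
  universe <- names(a)
  for (b in list(b1, b2)) {
    missing <- setdiff(universe, names(b))
    if (length(missing)) {
      stop(sprintf("transcript '%s' missing from a count matrix",
                   missing[1L]))
    }
  }
  okB <- if (config$anyDataset) {
    b1[universe] <= config$maxReadsSpeciesB |
      b2[universe] <= config$maxReadsSpeciesB
  } else {
    b1[universe] <= config$maxReadsSpeciesB &
      b2[universe] <= config$maxReadsSpeciesB
  }
  sort(universe[a >= config$minReadsSpeciesA & okB])
}

#' Gene Ontology over-representation by hypergeometric test
#'
#' For every term, the raw p-value is the hypergeometric upper tail
#' `P(X >= k)` with population size `N`, `K` term-annotated population
#' genes, study size `n` and study-term overlap `k`. P-values are adjusted
#' by the Benjamini-Hochberg step-up procedure over all tested terms.
#' Terms are treated as flat sets (no DAG propagation).
#'
#' @param study Character vector of study genes (must be a subset of
#'   `population`).
#' @param population Character vector of population genes.
#' @param termMap Data.frame with columns `gene` and `term` (one row per
#'   annotation); genes outside the population are ignored.
#' @param termNames Optional named character vector term -> label.
#' @return Data.frame with `term`, `label` (if supplied), `K`
#'   (population genes with the term), `k` (study genes with the term),
#'   `p` and `p_adj`, sorted by `p`.
#' @export
goOverrepresentation <- function(study, population, termMap,
                                 termNames = NULL) {
  study <- unique(study)
  population <- unique(population)
  outside <- setdiff(study, population)
  if (length(outside)) {
    stop(sprintf("study gene '%s' is not in the population", outside[1L]))
  }
  termMap <- termMap[termMap$gene %in% population, , drop = FALSE]
  N <- length(population)
  n <- length(study)
  terms <- unique(termMap$term)
  K <- vapply(terms, function(t)
    length(unique(termMap$gene[termMap$term == t])), integer(1))
  k <- vapply(terms, function(t)
    length(intersect(study, termMap$gene[termMap$term == t])), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, K = K, k = k, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"))
  if (!is.null(termNames)) {
    out$label <- unname(termNames[out$term])
    out <- out[, c("term", "label", "K", "k", "p", "p_adj")]
  }
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
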