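## Disease-gene enrichment of lipid-associated supersets/subnetworks.

#' Exact one-sided enrichment p for a 2x2 table
#'
#' The kernel shared by [fisherEnrichment()], [annotateSuperset()] and
#' [kdaTest()]: the hypergeometric upper tail `P[X >= overlap]` when drawing
#' `nQuery` genes from a universe of `nUniverse` containing `nTerm`
#' successes.  Identical to the one-sided (greater) Fisher exact test p.
#'
#' @param overlap observed intersection size(s); vectorized.
#' @param nQuery,nTerm,nUniverse the remaining margins of the table.
#' @return numeric vector of upper-tail probabilities.
#' @export
hyperEnrichmentP <- function(overlap, nQuery, nTerm, nUniverse) {
  phyper(overlap - 1, nTerm, nUniverse - nTerm, nQuery, lower.tail = FALSE)
}

#' One-sided Fisher exact enrichment of two gene sets in a universe
#'
#' Tests whether `query` is enriched for `disease` genes within `universe`
#' via the one-sided Fisher exact test on the 2x2 table (in query / not x in
#' disease / not), i.e. the hypergeometric upper tail `P[X >= overlap]`.  The
#' odds ratio uses the standard cross-product, with 0 or infinity allowed on
#' zero margins.  Disease gene lists are expected to be pre-filtered by the
#' caller (e.g. reported association P < 1e-5).
#'
#' @param query,disease character vectors of gene ids; both must be subsets
#'   of `universe`.
#' @param universe character vector of genes forming the sampling frame
#'   (conventionally all genes in the trait's marker-gene mapping).
#' @return list with elements overlap, odds_ratio and pvalue.
#' @export
fisherEnrichment <- function(query, disease, universe) {
  query <- unique(normalizeGeneIds(query))
  disease <- unique(normalizeGeneIds(disease))
  universe <- unique(normalizeGeneIds(universe))
  if (!all(query %in% universe))
    stop("validation error: query genes missing from universe")
  if (!all(disease %in% universe))
    stop("validation error: disease genes missing from universe")
  N <- length(universe)
  a <- length(intersect(query, disease))
  b <- length(query) - a
  cc <- length(disease) - a
  d <- N - a - b - cc
  orNum <- a * d; orDen <- b * cc
  oddsRatio <- if (orDen == 0) {
    if (orNum == 0) NaN else Inf
  } else orNum / orDen
  p <- hyperEnrichmentP(a, length(query), length(disease), N)
  list(overlap = a, odds_ratio = oddsRatio, pvalue = p)
}

#' Superset-by-disease enrichment matrix
#'
#' Runs [fisherEnrichment()] for every (superset, disease) pair and applies
#' Bonferroni correction with `m = n_supersets * n_diseases`.
#'
#' @param supersets a [GeneSetList-class] (typically a
#'   [SupersetList-class]).
#' @param diseaseSets a [GeneSetList-class] of disease susceptibility genes.
#' @param universe character vector of genes forming the sampling frame.
#'   Genes outside it are dropped from the tested sets (they could never have
#'   entered the results).
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with columns superset, disease, overlap, odds_ratio,
#'   pvalue, bonferroni_p, significant.
#' @export
enrichmentMatrix <- function(supersets, diseaseSets, universe, alpha = 0.05) {
  stopifnot(is(supersets, "GeneSetList"), is(diseaseSets, "GeneSetList"))
  universe <- unique(normalizeGeneIds(universe))
  ns <- nSets(supersets); nd <- nSets(diseaseSets)
  if (ns == 0 || nd == 0)
    return(data.frame(superset = character(0), disease = character(0),
                      overlap = integer(0), odds_ratio = numeric(0),
                      pvalue = numeric(0), bonferroni_p = numeric(0),
                      significant = logical(0)))
  m <- ns * nd
  grid <- expand.grid(si = seq_len(ns), di = seq_len(nd))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    si <- grid$si[r]; di <- grid$di[r]
    q <- intersect(normalizeGeneIds(supersets@genes[[si]]), universe)
    dz <- intersect(normalizeGeneIds(diseaseSets@genes[[di]]), universe)
    fe <- if (length(q) == 0 || length(dz) == 0)
      list(overlap = 0L, odds_ratio = NaN, pvalue = 1) else
      fisherEnrichment(q, dz, universe)
    data.frame(superset = supersets@setId[si],
               disease = diseaseSets@setId[di],
               overlap = as.integer(fe$overlap),
               odds_ratio = fe$odds_ratio, pvalue = fe$pvalue,
               bonferroni_p = min(1, fe$pvalue * m),
               significant = fe$pvalue * m < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pvalue, out$superset, out$disease), , drop = FALSE]
  rownames(out) <- NULL
  out
}
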