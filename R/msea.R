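## Marker Set Enrichment Analysis: quantile-cutoff statistic over the
## -log10(p) distribution of a gene set's mapped markers, against a
## marker-count-matched permutation null.

#' Quantile cutoffs on the background -log10(p) distribution
#'
#' `threshold[j]` is the `quantileLevels[j]` quantile of -log10(p) over the
#' background markers (all markers in the pruned mapping); thresholds are
#' non-decreasing by construction.
#'
#' @param backgroundP numeric vector of background marker p-values in (0, 1].
#' @param quantileLevels ascending fractions in (0, 1).
#' @return numeric vector of thresholds on the -log10(p) scale.
#' @export
computeCutoffs <- function(backgroundP, quantileLevels) {
  if (length(backgroundP) < 10)
    stop("background must contain at least 10 markers")
  if (any(backgroundP <= 0 | backgroundP > 1))
    stop("background p-values must lie in (0, 1]")
  quantile(-log10(backgroundP), probs = quantileLevels, names = FALSE)
}

#' The MSEA enrichment statistic
#'
#' Chi-square-like sum of standardized observed-minus-expected marker counts
#' across the quantile levels:
#' \deqn{X = \sum_j (O_j - E_j) / \sqrt{E_j + \kappa}}
#' where `kappa` stabilizes near-empty tail bins.
#'
#' @param observed,expected non-negative counts per quantile level (equal
#'   length).
#' @param kappa non-negative stabilizer (default 1).
#' @return the statistic X (a single number).
#' @examples
#' mseaStatistic(9, 4, kappa = 1)   # 5 / sqrt(5)
#' @export
mseaStatistic <- function(observed, expected, kappa = 1) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  if (any(observed < 0) || any(expected < 0))
    stop("counts must be non-negative")
  if (kappa < 0) stop("kappa must be >= 0")
  sum((observed - expected) / sqrt(expected + kappa))
}

#' Build the gene-to-marker index for enrichment testing
#'
#' Joins the (pruned) marker-gene map with the GWAS p-values.  Only markers
#' present in both the map and the GWAS table enter the index, so the
#' background distribution is exactly the mapped markers; markers are
#' deduplicated within each gene.  Map markers absent from the GWAS table are
#' recorded in the `"unmapped_in_gwas"` attribute.
#'
#' @param map a [MarkerGeneMap-class] (typically after [pruneMap()]).
#' @param markers data.frame as from [readGwas()].
#' @return A [GeneMarkerIndex-class].
#' @export
buildGeneMarkerIndex <- function(map, markers) {
  stopifnot(is(map, "MarkerGeneMap"), is.data.frame(markers))
  pairs <- mapPairs(map)
  inGwas <- pairs$marker_id %in% markers$marker_id
  missing <- unique(pairs$marker_id[!inGwas])
  pairs <- pairs[inGwas, , drop = FALSE]
  ids <- unique(pairs$marker_id)
  sel <- match(ids, markers$marker_id)
  pv <- markers$pvalue[sel]
  idx <- match(pairs$marker_id, ids)
  geneMarkers <- lapply(split(idx, pairs$gene_id), function(v)
    sort(unique(v)))
  res <- new("GeneMarkerIndex", geneMarkers = geneMarkers,
             markerIds = ids, pvalues = pv, mlp = -log10(pv))
  attr(res, "unmapped_in_gwas") <- missing
  res
}

## Shared pre-computation for one index + parameter set: thresholds, per-
## marker level index (number of thresholds at or below its -log10 p),
## marker-count bins for the matched null.
.mseaContext <- function(index, params) {
  thr <- computeCutoffs(index@pvalues, params@quantileLevels)
  levelIdx <- findInterval(index@mlp, thr)
  nm <- lengths(index@geneMarkers)
  breaks <- unique(quantile(nm, c(0.25, 0.5, 0.75), names = FALSE))
  bin <- findInterval(nm, breaks, left.open = TRUE) + 1L
  list(thr = thr, levelIdx = levelIdx, nLevels = length(thr),
       oneMinusQ = 1 - params@quantileLevels,
       binOf = bin, binMembers = split(seq_along(nm), bin))
}

## Statistic for the gene collection given as integer indices into
## index@geneMarkers.
.mseaXFor <- function(geneIdx, index, ctx, kappa) {
  u <- unique(unlist(index@geneMarkers[geneIdx], use.names = FALSE))
  tab <- tabulate(ctx$levelIdx[u], nbins = ctx$nLevels)
  O <- rev(cumsum(rev(tab)))
  E <- length(u) * ctx$oneMinusQ
  list(X = sum((O - E) / sqrt(E + kappa)), O = O, E = E,
       nMarkers = length(u))
}

.skipRecord <- function(setId, reason) {
  list(set_id = setId, n_genes_used = NA_integer_, n_markers = NA_integer_,
       observed = NULL, expected = NULL, X = NA_real_, pvalue = NA_real_,
       null_mean = NA_real_, null_sd = NA_real_,
       status = paste0("skipped:", reason))
}

#' Test one gene set for marker-set enrichment
#'
#' Computes the observed quantile-cutoff counts of the set's unique mapped
#' markers, the expected counts `E_j = n_markers * (1 - quantileLevels[j])`,
#' the statistic X (see [mseaStatistic()]), and a one-sided (enrichment-only)
#' p-value against a null of random gene collections of the same gene count.
#' By default the null collections are sampled within marker-count quartile
#' bins, so the null preserves the set's marker-count profile (gene-size bias
#' correction); the empirical p carries a +1 pseudocount:
#' `p = (1 + #\{X_null >= X_obs\}) / (nPerm + 1)`.
#'
#' A set intersecting the index in fewer than `minGenes` (or more than
#' `maxGenes`) genes, or entirely unmapped, yields a skip record (status
#' `"skipped:<reason>"`), not an error.
#'
#' @param genes character vector of the set's gene ids.
#' @param index a [GeneMarkerIndex-class].
#' @param params an [MseaParams-class].
#' @param setId identifier carried into the result.
#' @param exhaustive if TRUE, enumerate all same-size gene collections
#'   instead of sampling (feasible only for tiny universes); the p-value is
#'   then the exact fraction of collections with `X >= X_obs`.
#' @param .fromRun internal: skip seeding (used by [runMsea()], which seeds
#'   once for the whole collection).
#' @return list with elements set_id, n_genes_used, n_markers, observed,
#'   expected, X, pvalue, null_mean, null_sd, status.
#' @export
mseaTest <- function(genes, index, params = MseaParams(), setId = "set",
                     exhaustive = FALSE, .fromRun = FALSE) {
  stopifnot(is(index, "GeneMarkerIndex"), is(params, "MseaParams"))
  ctx <- .mseaContext(index, params)
  if (!.fromRun) set.seed(params@seed)
  .mseaTestOne(genes, index, params, ctx, setId, exhaustive)
}

.mseaTestOne <- function(genes, index, params, ctx, setId, exhaustive) {
  genesUsed <- intersect(normalizeGeneIds(genes), names(index@geneMarkers))
  k <- length(genesUsed)
  if (k == 0) return(.skipRecord(setId, "no_mapped_genes"))
  if (k < params@minGenes) return(.skipRecord(setId, "too_few_mapped_genes"))
  if (k > params@maxGenes) return(.skipRecord(setId, "too_many_mapped_genes"))
  geneIdx <- match(genesUsed, names(index@geneMarkers))
  obs <- .mseaXFor(geneIdx, index, ctx, params@kappa)

  nGenes <- length(index@geneMarkers)
  if (exhaustive) {
    if (choose(nGenes, k) > 2e5)
      stop("exhaustive enumeration infeasible: choose(nGenes, k) too large")
    combos <- combn(nGenes, k)
    xNull <- apply(combos, 2L, function(ix)
      .mseaXFor(ix, index, ctx, params@kappa)$X)
    pval <- mean(xNull >= obs$X)
  } else {
    xNull <- numeric(params@nPerm)
    if (params@matchBins) {
      cnt <- table(ctx$binOf[geneIdx])
      bins <- as.integer(names(cnt))
      members <- ctx$binMembers[as.character(bins)]
      need <- as.integer(cnt)
      for (i in seq_len(params@nPerm)) {
        draw <- unlist(lapply(seq_along(bins), function(b) {
          mb <- members[[b]]
          mb[sample.int(length(mb), need[b])]
        }), use.names = FALSE)
        xNull[i] <- .mseaXFor(draw, index, ctx, params@kappa)$X
      }
    } else {
      for (i in seq_len(params@nPerm))
        xNull[i] <- .mseaXFor(sample.int(nGenes, k), index, ctx,
                              params@kappa)$X
    }
    pval <- if (params@pMode == "empirical") {
      (1 + sum(xNull >= obs$X)) / (params@nPerm + 1)
    } else {
      s <- stats::sd(xNull)
      if (s == 0) 1 else pnorm(obs$X, mean = mean(xNull), sd = s,
                               lower.tail = FALSE)
    }
  }
  list(set_id = setId, n_genes_used = k, n_markers = obs$nMarkers,
       observed = obs$O, expected = obs$E, X = obs$X, pvalue = pval,
       null_mean = mean(xNull), null_sd = stats::sd(xNull), status = "ok")
}

#' Run MSEA over a collection of gene sets
#'
#' Seeds the RNG once from `params@seed`, tests every set in order (so the
#' whole table is reproducible bit-for-bit given the same inputs and seed),
#' and applies Benjamini-Hochberg FDR across the tested (non-skipped) sets.
#'
#' @param gsl a [GeneSetList-class].
#' @param index a [GeneMarkerIndex-class].
#' @param params an [MseaParams-class].
#' @return data.frame with columns set_id, n_genes_used, n_markers, X,
#'   pvalue, fdr, status; skipped sets carry NA statistics and their skip
#'   reason in status.
#' @export
runMsea <- function(gsl, index, params = MseaParams()) {
  stopifnot(is(gsl, "GeneSetList"))
  ctx <- .mseaContext(index, params)
  set.seed(params@seed)
  rows <- lapply(seq_len(nSets(gsl)), function(i)
    .mseaTestOne(gsl@genes[[i]], index, params, ctx, gsl@setId[i],
                 exhaustive = FALSE))
  res <- data.frame(
    set_id = vapply(rows, `[[`, "", "set_id"),
    n_genes_used = vapply(rows, `[[`, NA_integer_, "n_genes_used"),
    n_markers = vapply(rows, `[[`, NA_integer_, "n_markers"),
    X = vapply(rows, `[[`, NA_real_, "X"),
    pvalue = vapply(rows, `[[`, NA_real_, "pvalue"),
    fdr = NA_real_,
    status = vapply(rows, `[[`, "", "status"),
    stringsAsFactors = FALSE)
  ok <- res$status == "ok"
  if (any(ok)) res$fdr[ok] <- bhFdr(res$pvalue[ok])
  res
}

#' Benjamini-Hochberg step-up FDR
#'
#' `q_i = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j)`, clipped at
#' 1; input order is preserved.  Thin wrapper over
#' `stats::p.adjust(method = "BH")` kept as the module's named surface.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same order as the input.
#' @export
bhFdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Intersect significant sets across two independent datasets
#'
#' Sets significant (FDR below the threshold) in both of two independently
#' analyzed datasets.  Under independence the FDR of the intersection is
#' bounded by the product of the two thresholds (e.g. 10\% x 10\% = 1\%;
#' 10\% x 25\% = 2.5\%).
#'
#' @param resultsA,resultsB data.frames from [runMsea()] (need set_id and
#'   fdr).
#' @param fdrMaxA FDR threshold applied to `resultsA` (default 0.10).
#' @param fdrMaxB FDR threshold applied to `resultsB` (default `fdrMaxA`).
#' @return list with `setIds` (sorted ids significant in both) and
#'   `combinedFdrBound` (= fdrMaxA * fdrMaxB).
#' @examples
#' a <- data.frame(set_id = c("S1", "S2"), fdr = c(0.05, 0.5))
#' b <- data.frame(set_id = c("S1", "S2"), fdr = c(0.02, 0.02))
#' combineTwoDatasets(a, b)   # S1 only; bound 0.01
#' @export
combineTwoDatasets <- function(resultsA, resultsB, fdrMaxA = 0.10,
                               fdrMaxB = fdrMaxA) {
  sigA <- resultsA$set_id[!is.na(resultsA$fdr) & resultsA$fdr < fdrMaxA]
  sigB <- resultsB$set_id[!is.na(resultsB$fdr) & resultsB$fdr < fdrMaxB]
  list(setIds = sort(intersect(sigA, sigB)),
       combinedFdrBound = fdrMaxA * fdrMaxB)
}
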