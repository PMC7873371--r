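## Redundancy merging of significant gene sets into supersets, functional
## annotation by Fisher exact test, and second-round confirmation.

#' Overlap coefficient between two gene sets
#'
#' `|a intersect b| / min(|a|, |b|)`: 1 for nested sets, 0 for disjoint ones.
#' Preferred over Jaccard here because module-in-pathway nesting should count
#' as full redundancy.
#'
#' @param a,b non-empty character vectors of gene ids.
#' @return the overlap coefficient in [0, 1].
#' @export
overlapCoefficient <- function(a, b) {
  a <- unique(normalizeGeneIds(a)); b <- unique(normalizeGeneIds(b))
  if (length(a) == 0 || length(b) == 0)
    stop("overlap coefficient is undefined for empty sets")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Merge overlapping gene sets into non-redundant supersets
#'
#' Iterative agglomeration: while any pair of current clusters has overlap
#' coefficient >= `rho`, the maximal-coefficient pair is merged into the
#' union of its genes (ties broken by the lexicographically smallest pair of
#' cluster keys, where a cluster's key is its smallest member set id, so the
#' procedure is deterministic).  On termination all supersets are pairwise
#' below `rho`; member provenance is retained and the union of output genes
#' equals the union of input genes.
#'
#' @param gsl a [GeneSetList-class] (typically the significant sets of one
#'   trait).
#' @param rho redundancy threshold in (0, 1] (default 0.33).
#' @param idPrefix prefix for superset identifiers (default "SS").
#' @return A [SupersetList-class].
#' @examples
#' gsl <- GeneSetList(list(A = letters[1:10], B = letters[2:11],
#'                         C = LETTERS[11:24]))
#' setIds(mergeGeneSets(gsl, rho = 0.33))
#' @export
mergeGeneSets <- function(gsl, rho = 0.33, idPrefix = "SS") {
  stopifnot(is(gsl, "GeneSetList"))
  if (!is.numeric(rho) || rho <= 0 || rho > 1)
    stop("rho must lie in (0, 1]")
  clusters <- lapply(seq_len(nSets(gsl)), function(i)
    list(ids = gsl@setId[i], genes = gsl@genes[[i]], key = gsl@setId[i]))
  repeat {
    n <- length(clusters)
    if (n < 2) break
    best <- NULL; bestCoef <- -1
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      co <- overlapCoefficient(clusters[[i]]$genes, clusters[[j]]$genes)
      if (co < rho) next
      ki <- clusters[[i]]$key; kj <- clusters[[j]]$key
      pair <- sort(c(ki, kj))
      better <- co > bestCoef ||
        (co == bestCoef && (pair[1] < best$pair[1] ||
          (pair[1] == best$pair[1] && pair[2] < best$pair[2])))
      if (better) {
        best <- list(i = i, j = j, pair = pair)
        bestCoef <- co
      }
    }
    if (is.null(best)) break
    ci <- clusters[[best$i]]; cj <- clusters[[best$j]]
    merged <- list(ids = sort(unique(c(ci$ids, cj$ids))),
                   genes = sort(unique(c(ci$genes, cj$genes))),
                   key = min(ci$key, cj$key))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  keys <- vapply(clusters, `[[`, "", "key")
  clusters <- clusters[order(keys)]
  ids <- sprintf("%s%02d", idPrefix, seq_along(clusters))
  srcByIds <- setNames(gsl@source, gsl@setId)
  new("SupersetList",
      setId = ids,
      description = vapply(clusters, function(cl)
        paste(cl$ids, collapse = ";"), ""),
      source = vapply(clusters, function(cl)
        paste(sort(unique(srcByIds[cl$ids])), collapse = ";"), ""),
      genes = lapply(clusters, `[[`, "genes"),
      memberSets = lapply(clusters, `[[`, "ids"),
      annotations = rep(list(data.frame()), length(clusters)))
}

#' Annotate a superset with enriched functional terms
#'
#' For every annotation set, a one-sided Fisher exact test on the 2x2 table
#' (in superset / not x in term / not); terms are kept iff the
#' Bonferroni-corrected p (p times the number of terms) is below `alpha`,
#' sorted by p.
#'
#' @param genes character vector: the superset's genes.
#' @param annotationSets a [GeneSetList-class] of functional terms.
#' @param universe character vector of all genes forming the sampling frame;
#'   must contain the superset.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with columns term, overlap, fisher_p, bonferroni_p
#'   (only the retained terms, sorted by fisher_p).
#' @export
annotateSuperset <- function(genes, annotationSets, universe, alpha = 0.05) {
  stopifnot(is(annotationSets, "GeneSetList"))
  genes <- unique(normalizeGeneIds(genes))
  universe <- unique(normalizeGeneIds(universe))
  if (!all(genes %in% universe))
    stop("universe must contain every superset gene")
  nTerms <- nSets(annotationSets)
  if (nTerms == 0)
    return(data.frame(term = character(0), overlap = integer(0),
                      fisher_p = numeric(0), bonferroni_p = numeric(0)))
  term <- annotationSets@setId
  p <- ov <- numeric(nTerms)
  for (i in seq_len(nTerms)) {
    tg <- intersect(annotationSets@genes[[i]], universe)
    if (length(tg) > length(universe))
      stop("term larger than the universe")
    ov[i] <- length(intersect(genes, tg))
    p[i] <- hyperEnrichmentP(ov[i], length(genes), length(tg),
                             length(universe))
  }
  bonf <- pmin(1, p * nTerms)
  keep <- which(p * nTerms < alpha)
  keep <- keep[order(p[keep], term[keep])]
  data.frame(term = term[keep], overlap = as.integer(ov[keep]),
             fisher_p = p[keep], bonferroni_p = bonf[keep],
             stringsAsFactors = FALSE)
}

#' Confirm supersets by a second enrichment round
#'
#' Each superset is re-tested with [mseaTest()] against the same index; a
#' superset passes when its p-value survives Bonferroni correction for the
#' number of supersets tested (`pvalue * n < alpha`).
#'
#' @param supersets a [SupersetList-class] (or any [GeneSetList-class]).
#' @param index a [GeneMarkerIndex-class].
#' @param params an [MseaParams-class].
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with columns superset_id, n_genes_used, n_markers, X,
#'   pvalue, bonferroni_p, pass (logical; NA for skipped supersets).
#' @export
confirmSupersets <- function(supersets, index, params = MseaParams(),
                             alpha = 0.05) {
  stopifnot(is(supersets, "GeneSetList"))
  n <- nSets(supersets)
  ctx <- .mseaContext(index, params)
  set.seed(params@seed)
  rows <- lapply(seq_len(n), function(i)
    .mseaTestOne(supersets@genes[[i]], index, params, ctx,
                 supersets@setId[i], exhaustive = FALSE))
  pv <- vapply(rows, `[[`, NA_real_, "pvalue")
  data.frame(
    superset_id = supersets@setId,
    n_genes_used = vapply(rows, `[[`, NA_integer_, "n_genes_used"),
    n_markers = vapply(rows, `[[`, NA_integer_, "n_markers"),
    X = vapply(rows, `[[`, NA_real_, "X"),
    pvalue = pv,
    bonferroni_p = pmin(1, pv * n),
    pass = ifelse(is.na(pv), NA, pv * n < alpha),
    stringsAsFactors = FALSE)
}
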