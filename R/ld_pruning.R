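## Association-aware greedy pruning of markers in linkage disequilibrium.

#' Prune markers in LD, preferentially keeping the strongest associations
#'
#' Greedy best-association-first selection: markers are visited in ascending
#' p-value order (ties broken lexicographically by marker id, for
#' determinism) and a marker is accepted iff its r-squared with every
#' previously accepted marker is below `r2Max`.  Pairs absent from the LD
#' table count as r2 = 0 (unlinked).  Within any clique of mutually linked
#' markers this keeps exactly the smallest-p member; the output is
#' deterministic and preserves acceptance order.
#'
#' Each study (e.g. a genome-wide scan and an independent chip-based scan) is
#' pruned independently by calling this once per study.
#'
#' @param markers data.frame as from [readGwas()]; every marker needs a
#'   pvalue.
#' @param ld an [LDTable-class].
#' @param r2Max LD cutoff in (0, 1]; markers at or above it are considered
#'   redundant (default 0.5).
#' @return character vector of kept marker ids, in acceptance order.
#' @examples
#' m <- data.frame(marker_id = c("A", "B"), pvalue = c(1e-8, 1e-4))
#' ld <- LDTable(data.frame(marker_a = "A", marker_b = "B", r2 = 0.8))
#' pruneLd(m, ld)   # keeps only A
#' @export
pruneLd <- function(markers, ld, r2Max = 0.5) {
  stopifnot(is.data.frame(markers), is(ld, "LDTable"))
  if (!is.numeric(r2Max) || length(r2Max) != 1 || r2Max <= 0 || r2Max > 1)
    stop("configuration error: r2Max must lie in (0, 1]")
  if (anyNA(markers$pvalue))
    stop("every marker must have a pvalue")
  if (nrow(markers) == 0) return(character(0))
  ord <- order(markers$pvalue, markers$marker_id)
  ids <- markers$marker_id[ord]

  ## adjacency over high-LD pairs only: the accept test needs just the
  ## partners whose r2 >= r2Max
  p <- ld@pairs
  p <- p[p$r2 >= r2Max & p$marker_a != p$marker_b, , drop = FALSE]
  nbrs <- new.env(parent = emptyenv())
  if (nrow(p) > 0) {
    ends <- data.frame(a = c(p$marker_a, p$marker_b),
                       b = c(p$marker_b, p$marker_a),
                       stringsAsFactors = FALSE)
    sp <- split(ends$b, ends$a)
    for (k in names(sp)) assign(k, unique(sp[[k]]), envir = nbrs)
  }

  accepted <- new.env(parent = emptyenv())
  kept <- character(0)
  for (id in ids) {
    linked <- if (exists(id, envir = nbrs, inherits = FALSE))
      get(id, envir = nbrs) else character(0)
    clash <- any(vapply(linked, exists, TRUE, envir = accepted,
                        inherits = FALSE))
    if (!clash) {
      assign(id, TRUE, envir = accepted)
      kept <- c(kept, id)
    }
  }
  kept
}

#' Restrict a marker-gene map to pruned markers
#'
#' Drops map entries whose marker was removed by LD pruning.  Genes left with
#' zero markers are reported via [message()] and the `"dropped_genes"`
#' attribute (the audit trail for downstream set-size bookkeeping).
#'
#' @param map a [MarkerGeneMap-class].
#' @param kept character vector of retained marker ids (from [pruneLd()]).
#' @return A [MarkerGeneMap-class] restricted to `kept`.
#' @export
pruneMap <- function(map, kept) {
  stopifnot(is(map, "MarkerGeneMap"), is.character(kept))
  e <- mapEntries(map)
  out <- e[e$marker_id %in% kept, , drop = FALSE]
  dropped <- setdiff(unique(e$gene_id), unique(out$gene_id))
  if (length(dropped) > 0)
    message(sprintf("pruneMap: %d gene(s) left without markers",
                    length(dropped)))
  res <- MarkerGeneMap(out)
  attr(res, "dropped_genes") <- dropped
  res
}
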