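#' Accessors for netMSEA containers
#'
#' Small accessor layer over the S4 containers: set ids, member genes, map
#' entries, LD pairs, network edges and nodes, superset provenance.
#'
#' @param x a netMSEA container object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("nSets", function(x) standardGeneric("nSets"))

#' @rdname accessors
#' @export
setGeneric("setSources", function(x) standardGeneric("setSources"))

#' @rdname accessors
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname accessors
#' @export
setGeneric("mapEntries", function(x) standardGeneric("mapEntries"))

#' @rdname accessors
#' @export
setGeneric("mapPairs", function(x) standardGeneric("mapPairs"))

#' @rdname accessors
#' @export
setGeneric("ldPairs", function(x) standardGeneric("ldPairs"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("memberSets", function(x) standardGeneric("memberSets"))

#' @rdname accessors
#' @export
setGeneric("supersetAnnotations",
           function(x) standardGeneric("supersetAnnotations"))

#' @rdname accessors
setMethod("setIds", "GeneSetList", function(x) x@setId)

#' @rdname accessors
setMethod("geneSets", "GeneSetList",
          function(x) setNames(x@genes, x@setId))

#' @rdname accessors
setMethod("nSets", "GeneSetList", function(x) length(x@setId))

#' @rdname accessors
setMethod("setSources", "GeneSetList", function(x) setNames(x@source, x@setId))

#' @rdname accessors
setMethod("setDescriptions", "GeneSetList",
          function(x) setNames(x@description, x@setId))

#' @rdname accessors
setMethod("mapEntries", "MarkerGeneMap", function(x) x@entries)

#' @rdname accessors
setMethod("mapPairs", "MarkerGeneMap", function(x) {
  e <- x@entries[, c("marker_id", "gene_id")]
  e <- e[!duplicated(paste(e$marker_id, e$gene_id, sep = "\r")), ,
         drop = FALSE]
  rownames(e) <- NULL
  e
})

#' @rdname accessors
setMethod("ldPairs", "LDTable", function(x) x@pairs)

#' @rdname accessors
setMethod("networkEdges", "DirectedGeneNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("networkNodes", "DirectedGeneNetwork",
          function(x) sort(unique(c(x@edges$tail, x@edges$head))))

#' @rdname accessors
setMethod("memberSets", "SupersetList",
          function(x) setNames(x@memberSets, x@setId))

#' @rdname accessors
setMethod("supersetAnnotations", "SupersetList",
          function(x) setNames(x@annotations, x@setId))

## ---- show methods -------------------------------------------------------

setMethod("show", "GeneSetList", function(object) {
  cat(class(object), "with", length(object@setId), "gene sets\n")
  if (length(object@setId) > 0) {
    sz <- lengths(object@genes)
    cat("  set sizes:", min(sz), "..", max(sz),
        sprintf("(median %g)\n", stats::median(sz)))
    show_n <- min(5L, length(object@setId))
    cat("  ids:", paste(head(object@setId, show_n), collapse = ", "),
        if (length(object@setId) > show_n) "..." else "", "\n")
  }
  invisible(NULL)
})

setMethod("show", "MarkerGeneMap", function(object) {
  e <- object@entries
  cat("MarkerGeneMap with", nrow(e), "entries:",
      length(unique(e$marker_id)), "markers,",
      length(unique(e$gene_id)), "genes,",
      length(unique(e$source)), "source tag(s)\n")
  invisible(NULL)
})

setMethod("show", "LDTable", function(object) {
  cat("LDTable with", nrow(object@pairs), "marker pairs\n")
  invisible(NULL)
})

setMethod("show", "DirectedGeneNetwork", function(object) {
  e <- object@edges
  cat("DirectedGeneNetwork with", nrow(e), "edges over",
      length(unique(c(e$tail, e$head))), "nodes\n")
  invisible(NULL)
})

setMethod("show", "GeneMarkerIndex", function(object) {
  cat("GeneMarkerIndex:", length(object@geneMarkers), "genes,",
      length(object@markerIds), "markers\n")
  invisible(NULL)
})

setMethod("show", "MseaParams", function(object) {
  cat("MseaParams:", length(object@quantileLevels), "quantile levels,",
      "kappa =", object@kappa, ", nPerm =", object@nPerm,
      ", pMode =", object@pMode, "\n")
  invisible(NULL)
})

setMethod("show", "KdaParams", function(object) {
  cat("KdaParams: depth", object@depth, object@direction,
      ", minNbhd =", object@minNbhd, ", fdrMax =", object@fdrMax,
      ", edgeMinStudies =", object@edgeMinStudies, "\n")
  invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nMarkers, "markers,", object@nGenes, "genes,",
      object@nSets, "sets (", object@nSignalSets, "signal ),",
      object@netNodes, "network nodes, seed", object@seed, "\n")
  invisible(NULL)
})
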