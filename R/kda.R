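## Key driver analysis: hypergeometric enrichment of directed network
## neighborhoods for superset genes.

.asIgraph <- function(net) {
  e <- networkEdges(net)
  igraph::graph_from_data_frame(e[, c("tail", "head")], directed = TRUE)
}

.igraphMode <- function(direction)
  switch(direction, out = "out", `in` = "in", both = "all")

#' Directed neighborhood of a gene
#'
#' All nodes reachable from `gene` in at most `depth` steps following the
#' chosen edge direction, excluding the gene itself.
#'
#' @param net a [DirectedGeneNetwork-class].
#' @param gene a node identifier.
#' @param depth maximum number of steps (1..3; default 1).
#' @param direction "out" (follow edge direction; default), "in" or "both".
#' @return character vector of neighbor gene ids (sorted).
#' @export
nodeNeighborhood <- function(net, gene, depth = 1L,
                             direction = c("out", "in", "both")) {
  stopifnot(is(net, "DirectedGeneNetwork"))
  direction <- match.arg(direction)
  gene <- normalizeGeneIds(gene)
  nodes <- networkNodes(net)
  if (!gene %in% nodes)
    stop(sprintf("gene '%s' is not in the network", gene))
  g <- .asIgraph(net)
  nb <- igraph::ego(g, order = depth, nodes = gene,
                    mode = .igraphMode(direction), mindist = 1)[[1L]]
  sort(names(nb))
}

#' Key driver analysis of a gene superset on a directed network
#'
#' Scores every network node whose `depth`-step directed neighborhood has at
#' least `minNbhd` members: the overlap between the neighborhood and the
#' superset is compared with the expectation for a randomly selected gene via
#' the one-sided hypergeometric tail
#' `p = P[X >= n_overlap]` with population `N = n_nodes - 1`, success count
#' `K = |superset in network|` (minus one when the hub itself belongs to the
#' superset: the test conditions on the hub and concerns its neighbors only)
#' and `n_nbhd` draws.  BH FDR is applied across all tested nodes; a key
#' driver is a node with `fdr < fdrMax`.  Edges observed in fewer than
#' `edgeMinStudies` independent network studies are dropped before testing.
#' Edge weights are carried but unused (presence/absence across studies is
#' the filter; the test itself is unweighted).
#'
#' @param net a [DirectedGeneNetwork-class].
#' @param supersetGenes character vector of superset gene ids.
#' @param params a [KdaParams-class].
#' @return data.frame sorted by (pvalue, gene) with columns gene, n_nbhd,
#'   n_overlap, fold_enrichment, pvalue, fdr, is_kd.  Empty (with a message)
#'   when the superset does not intersect the network.
#' @export
kdaTest <- function(net, supersetGenes, params = KdaParams()) {
  stopifnot(is(net, "DirectedGeneNetwork"), is(params, "KdaParams"))
  e <- networkEdges(net)
  e <- e[e$n_studies >= params@edgeMinStudies, , drop = FALSE]
  empty <- data.frame(gene = character(0), n_nbhd = integer(0),
                      n_overlap = integer(0), fold_enrichment = numeric(0),
                      pvalue = numeric(0), fdr = numeric(0),
                      is_kd = logical(0))
  if (nrow(e) == 0) {
    message("kdaTest: no edges pass the study-support filter")
    return(empty)
  }
  net <- DirectedGeneNetwork(e)
  nodes <- networkNodes(net)
  S <- intersect(unique(normalizeGeneIds(supersetGenes)), nodes)
  K0 <- length(S)
  message(sprintf("kdaTest: %d of %d superset genes present in the network",
                  K0, length(unique(normalizeGeneIds(supersetGenes)))))
  if (K0 == 0) {
    message("kdaTest: superset does not intersect the network; no test run")
    return(empty)
  }
  g <- .asIgraph(net)
  nbhds <- igraph::ego(g, order = params@depth, nodes = nodes,
                       mode = .igraphMode(params@direction), mindist = 1)
  nN <- length(nodes)
  inS <- nodes %in% S
  sizes <- lengths(nbhds)
  tested <- which(sizes >= params@minNbhd)
  if (length(tested) == 0) {
    message("kdaTest: no node has a large enough neighborhood")
    return(empty)
  }
  ov <- vapply(tested, function(i)
    sum(names(nbhds[[i]]) %in% S), 0L)
  n <- sizes[tested]
  K <- K0 - as.integer(inS[tested])   # condition on the hub
  N <- nN - 1L
  p <- hyperEnrichmentP(ov, n, K, N)
  fold <- ifelse(K > 0, (ov / n) / (K / N), NA_real_)
  res <- data.frame(gene = nodes[tested], n_nbhd = as.integer(n),
                    n_overlap = as.integer(ov), fold_enrichment = fold,
                    pvalue = p, fdr = bhFdr(p), stringsAsFactors = FALSE)
  res$is_kd <- res$fdr < params@fdrMax
  res <- res[order(res$pvalue, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export the subnetwork around key drivers
#'
#' Edges incident to a key driver whose other endpoint belongs to the
#' superset or is itself a key driver, after the per-edge study-support
#' filter.  Each edge is annotated with whether its endpoints are key drivers
#' and with the head gene's best GWAS significance (minimum p over its mapped
#' markers) for downstream node sizing; NA when no mapping/GWAS is supplied
#' or the gene has no marker.
#'
#' @param net a [DirectedGeneNetwork-class].
#' @param kds non-empty character vector of key driver gene ids.
#' @param supersetGenes character vector of superset gene ids.
#' @param params a [KdaParams-class] (edgeMinStudies is the filter; 2 for
#'   reported subnetworks).
#' @param map optional [MarkerGeneMap-class] for gene-level GWAS annotation.
#' @param markers optional GWAS data.frame (needed with `map`).
#' @return data.frame with columns tail, head, n_studies, tail_is_kd,
#'   head_is_kd, head_best_gwas_p.
#' @export
exportSubnetwork <- function(net, kds, supersetGenes,
                             params = KdaParams(edgeMinStudies = 2L),
                             map = NULL, markers = NULL) {
  stopifnot(is(net, "DirectedGeneNetwork"))
  kds <- unique(normalizeGeneIds(kds))
  if (length(kds) == 0) stop("kds must be non-empty")
  S <- unique(normalizeGeneIds(supersetGenes))
  e <- networkEdges(net)
  e <- e[e$n_studies >= params@edgeMinStudies, , drop = FALSE]
  if (nrow(e) == 0) {
    warning("exportSubnetwork: no edges pass the study-support filter")
    return(data.frame(tail = character(0), head = character(0),
                      n_studies = integer(0), tail_is_kd = logical(0),
                      head_is_kd = logical(0),
                      head_best_gwas_p = numeric(0)))
  }
  keepSet <- union(S, kds)
  keep <- (e$tail %in% kds & e$head %in% keepSet) |
          (e$head %in% kds & e$tail %in% keepSet)
  e <- e[keep, , drop = FALSE]
  bestP <- NULL
  if (!is.null(map) && !is.null(markers)) {
    pairs <- mapPairs(map)
    pv <- markers$pvalue[match(pairs$marker_id, markers$marker_id)]
    ok <- !is.na(pv)
    bestP <- tapply(pv[ok], pairs$gene_id[ok], min)
  }
  out <- data.frame(tail = e$tail, head = e$head,
                    n_studies = e$n_studies,
                    tail_is_kd = e$tail %in% kds,
                    head_is_kd = e$head %in% kds,
                    head_best_gwas_p = if (is.null(bestP)) NA_real_ else
                      as.numeric(bestP[e$head]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
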