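#' @import methods
#' @importFrom stats quantile phyper dhyper pnorm p.adjust rbeta runif
#'   rgeom setNames
#' @importFrom utils read.delim write.table combn head
NULL

## Gene identifiers are normalized to uppercase symbol strings throughout;
## cross-species / cross-ID-system translation is the caller's job.
normalizeGeneIds <- function(x) toupper(trimws(as.character(x)))

#' Collection of named gene sets
#'
#' Container for pathways, coexpression modules, positive controls or disease
#' gene lists: parallel vectors of set id, free-text description and source
#' label, plus a list of member gene vectors.  Gene identifiers are
#' case-normalized to uppercase at construction; duplicate genes within a set
#' are collapsed.
#'
#' @slot setId character vector of unique set identifiers.
#' @slot description character vector, one free-text description per set.
#' @slot source character vector, provenance label per set (e.g. "pathway",
#'   "coexpression_module", "positive_control").
#' @slot genes list of character vectors, the member genes per set.
#'
#' @seealso [readGeneSetsGmt()], [mergeGeneSets()]
#' @export
setClass("GeneSetList",
  representation(setId = "character", description = "character",
                 source = "character", genes = "list"))

setValidity("GeneSetList", function(object) {
  n <- length(object@setId)
  if (length(object@description) != n || length(object@source) != n ||
      length(object@genes) != n)
    return("setId, description, source and genes must have equal length")
  if (anyDuplicated(object@setId))
    return(sprintf("duplicate set id: %s",
                   object@setId[duplicated(object@setId)][1L]))
  if (n > 0 && any(lengths(object@genes) == 0L))
    return("every gene set must be non-empty")
  TRUE
})

#' Construct a GeneSetList
#'
#' @param genes named list of character vectors (names become set ids), the
#'   member genes per set.  Genes are uppercased and deduplicated.
#' @param description optional character vector of descriptions (recycled
#'   `""`).
#' @param source optional character vector of source labels (recycled
#'   `"unspecified"`).
#' @return A [GeneSetList-class] object.
#' @examples
#' gsl <- GeneSetList(list(S1 = c("a", "B", "b"), S2 = c("C", "D")))
#' geneSets(gsl)
#' @export
GeneSetList <- function(genes, description = NULL, source = NULL) {
  if (is.null(names(genes)) && length(genes) > 0)
    stop("'genes' must be a named list (names are the set ids)")
  ids <- as.character(names(genes))
  g <- lapply(genes, function(v) unique(normalizeGeneIds(v)))
  names(g) <- NULL
  if (is.null(description)) description <- rep("", length(ids))
  if (is.null(source)) source <- rep("unspecified", length(ids))
  new("GeneSetList", setId = ids,
      description = rep_len(as.character(description), length(ids)),
      source = rep_len(as.character(source), length(ids)),
      genes = g)
}

#' Supersets: merged, non-redundant unions of gene sets
#'
#' Extends [GeneSetList-class] with the provenance of each superset (which
#' input sets were merged into it) and optional functional annotation tables
#' from [annotateSuperset()].
#'
#' @slot memberSets list of character vectors: input set ids merged into each
#'   superset.
#' @slot annotations list of data.frames (possibly empty), one per superset,
#'   as returned by [annotateSuperset()].
#' @export
setClass("SupersetList", contains = "GeneSetList",
  representation(memberSets = "list", annotations = "list"))

setValidity("SupersetList", function(object) {
  n <- length(object@setId)
  if (length(object@memberSets) != n)
    return("memberSets must have one entry per superset")
  if (length(object@annotations) != n)
    return("annotations must have one entry per superset")
  for (i in seq_len(n)) {
    if (length(object@memberSets[[i]]) == 0L)
      return("every superset must record at least one member set")
  }
  TRUE
})

#' Many-to-many marker-to-gene map
#'
#' One row per (marker, gene, source) triple.  A marker may map to several
#' genes and a gene may own several markers; a pair supported by k mapping
#' sources appears in k rows, one per source tag.  Optional columns `cis`
#' (logical; NA when the marker-gene distance is unknown) and `eqtl_fdr`.
#'
#' @slot entries data.frame with columns marker_id, gene_id, source and
#'   optionally cis, eqtl_fdr.
#' @seealso [mapByDistance()], [mapByEqtl()], [mapByRegulome()],
#'   [combineMappings()]
#' @export
setClass("MarkerGeneMap", representation(entries = "data.frame"))

setValidity("MarkerGeneMap", function(object) {
  e <- object@entries
  need <- c("marker_id", "gene_id", "source")
  if (!all(need %in% names(e)))
    return(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  key <- paste(e$marker_id, e$gene_id, e$source, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate (marker_id, gene_id, source) triple")
  if ("eqtl_fdr" %in% names(e)) {
    f <- e$eqtl_fdr
    if (any(!is.na(f) & (f < 0 | f > 1)))
      return("eqtl_fdr must lie in [0, 1]")
  }
  TRUE
})

#' Construct a MarkerGeneMap
#'
#' @param entries data.frame with columns marker_id, gene_id, source and
#'   optionally cis, eqtl_fdr.  Gene ids are uppercased; duplicate triples are
#'   collapsed.
#' @return A [MarkerGeneMap-class] object.
#' @export
MarkerGeneMap <- function(entries) {
  entries <- as.data.frame(entries)
  if (nrow(entries) == 0 && !all(c("marker_id", "gene_id", "source") %in% names(entries)))
    entries <- data.frame(marker_id = character(0), gene_id = character(0),
                          source = character(0))
  entries$marker_id <- as.character(entries$marker_id)
  entries$gene_id <- normalizeGeneIds(entries$gene_id)
  entries$source <- as.character(entries$source)
  key <- paste(entries$marker_id, entries$gene_id, entries$source, sep = "\r")
  entries <- entries[!duplicated(key), , drop = FALSE]
  rownames(entries) <- NULL
  new("MarkerGeneMap", entries = entries)
}

#' Sparse pairwise linkage-disequilibrium table
#'
#' Stores marker pairs with their r-squared.  Lookup is symmetric and a
#' missing pair is treated as r-squared 0 (absence of evidence = unlinked;
#' LD tables are sparse by construction).
#'
#' @slot pairs data.frame with columns marker_a, marker_b, r2 in [0, 1].
#' @seealso [pruneLd()], [r2Between()]
#' @export
setClass("LDTable", representation(pairs = "data.frame"))

setValidity("LDTable", function(object) {
  p <- object@pairs
  if (!all(c("marker_a", "marker_b", "r2") %in% names(p)))
    return("pairs must have columns marker_a, marker_b, r2")
  if (nrow(p) > 0 && (any(p$r2 < 0) || any(p$r2 > 1) || anyNA(p$r2)))
    return("r2 must lie in [0, 1]")
  TRUE
})

#' Construct an LDTable
#'
#' @param pairs data.frame with columns marker_a, marker_b, r2.
#' @return An [LDTable-class] object.
#' @export
LDTable <- function(pairs = data.frame(marker_a = character(0),
                                       marker_b = character(0),
                                       r2 = numeric(0))) {
  pairs <- as.data.frame(pairs)
  pairs$marker_a <- as.character(pairs$marker_a)
  pairs$marker_b <- as.character(pairs$marker_b)
  pairs$r2 <- as.numeric(pairs$r2)
  rownames(pairs) <- NULL
  new("LDTable", pairs = pairs)
}

#' Directed gene regulatory network
#'
#' Edge list of a directed, weighted network with per-edge study support
#' (number of independent network studies in which the edge was observed).
#' Self-loops are disallowed; the node set is the union of edge endpoints.
#'
#' @slot edges data.frame with columns tail, head, weight (>= 0) and
#'   n_studies (positive integer).
#' @seealso [readNetwork()], [kdaTest()], [nodeNeighborhood()]
#' @export
setClass("DirectedGeneNetwork", representation(edges = "data.frame"))

setValidity("DirectedGeneNetwork", function(object) {
  e <- object@edges
  need <- c("tail", "head", "weight", "n_studies")
  if (!all(need %in% names(e)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e) == 0) return(TRUE)
  if (any(e$tail == e$head)) return("self-loops are not allowed")
  if (any(e$weight < 0) || anyNA(e$weight)) return("weight must be >= 0")
  ns <- e$n_studies
  if (any(ns < 1) || any(ns != round(ns)) || anyNA(ns))
    return("n_studies must be a positive integer")
  TRUE
})

#' Construct a DirectedGeneNetwork
#'
#' @param edges data.frame with columns tail, head and optionally weight
#'   (default 1) and n_studies (default 1).  Gene ids are uppercased and
#'   duplicate (tail, head) edges collapsed to the maximal support.
#' @return A [DirectedGeneNetwork-class] object.
#' @export
DirectedGeneNetwork <- function(edges = data.frame(tail = character(0),
                                                   head = character(0))) {
  edges <- as.data.frame(edges)
  edges$tail <- normalizeGeneIds(edges$tail)
  edges$head <- normalizeGeneIds(edges$head)
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (is.null(edges$n_studies)) edges$n_studies <- rep(1L, nrow(edges))
  edges$weight <- as.numeric(edges$weight)
  edges$n_studies <- as.integer(edges$n_studies)
  key <- paste(edges$tail, edges$head, sep = "\r")
  if (anyDuplicated(key)) {
    o <- order(key, -edges$n_studies, -edges$weight)
    edges <- edges[o, , drop = FALSE]
    edges <- edges[!duplicated(paste(edges$tail, edges$head, sep = "\r")), ,
                   drop = FALSE]
    edges <- edges[order(edges$tail, edges$head), , drop = FALSE]
  }
  edges <- edges[, c("tail", "head", "weight", "n_studies")]
  rownames(edges) <- NULL
  new("DirectedGeneNetwork", edges = edges)
}

#' Gene-to-marker index for enrichment testing
#'
#' Post-pruning view joining the marker-gene map with the GWAS p-values:
#' per gene, the integer indices of its (deduplicated) markers; per marker,
#' its association p-value and -log10(p).
#'
#' @slot geneMarkers named list of integer vectors (indices into markerIds).
#' @slot markerIds character vector of marker identifiers.
#' @slot pvalues numeric vector of association p-values in (0, 1].
#' @slot mlp numeric vector, -log10(pvalues).
#' @seealso [buildGeneMarkerIndex()], [mseaTest()]
#' @export
setClass("GeneMarkerIndex",
  representation(geneMarkers = "list", markerIds = "character",
                 pvalues = "numeric", mlp = "numeric"))

setValidity("GeneMarkerIndex", function(object) {
  m <- length(object@markerIds)
  if (length(object@pvalues) != m || length(object@mlp) != m)
    return("pvalues and mlp must parallel markerIds")
  if (m > 0 && (any(object@pvalues <= 0) || any(object@pvalues > 1)))
    return("pvalues must lie in (0, 1]")
  for (g in object@geneMarkers) {
    if (anyDuplicated(g)) return("markers must be deduplicated within a gene")
    if (length(g) > 0 && (min(g) < 1 || max(g) > m))
      return("gene marker indices out of range")
  }
  TRUE
})

#' Parameters for Marker Set Enrichment Analysis
#'
#' @slot quantileLevels strictly ascending fractions in (0, 1): the quantiles
#'   of the background -log10(p) distribution at which observed and expected
#'   marker counts are compared.
#' @slot kappa non-negative stabilizer added to the expected count inside the
#'   square root of the statistic.
#' @slot nPerm number of null permutations (>= 100).
#' @slot seed integer RNG seed.
#' @slot minGenes,maxGenes set-size bounds; sets whose mapped-gene count falls
#'   outside are skipped with a recorded reason.
#' @slot pMode "empirical" (+1 pseudocount permutation p, default) or
#'   "gaussian" (normal tail from the null mean/sd).
#' @slot matchBins logical: sample null gene collections within marker-count
#'   quartile bins (gene-size bias correction, default TRUE).
#' @seealso [MseaParams()], [mseaTest()], [runMsea()]
#' @export
setClass("MseaParams",
  representation(quantileLevels = "numeric", kappa = "numeric",
                 nPerm = "integer", seed = "integer",
                 minGenes = "integer", maxGenes = "integer",
                 pMode = "character", matchBins = "logical"))

setValidity("MseaParams", function(object) {
  q <- object@quantileLevels
  if (length(q) < 1 || any(q <= 0) || any(q >= 1))
    return("quantileLevels must lie strictly inside (0, 1)")
  if (is.unsorted(q, strictly = TRUE))
    return("quantileLevels must be strictly ascending")
  if (object@kappa < 0) return("kappa must be >= 0")
  if (object@nPerm < 100L) return("nPerm must be >= 100")
  if (!object@pMode %in% c("empirical", "gaussian"))
    return("pMode must be 'empirical' or 'gaussian'")
  if (object@minGenes < 1L || object@maxGenes < object@minGenes)
    return("need 1 <= minGenes <= maxGenes")
  TRUE
})

#' Construct MSEA parameters
#'
#' Defaults: ten quantile levels \{0.50, 0.60, 0.70, 0.80, 0.90, 0.95, 0.975,
#' 0.99, 0.995, 0.999\}, kappa = 1, 1000 permutations, set-size bounds
#' 10..500, empirical p-values with a +1 pseudocount, marker-count-bin
#' matched null sampling.
#'
#' @param quantileLevels,kappa,nPerm,seed,minGenes,maxGenes,pMode,matchBins
#'   see [MseaParams-class].
#' @return An [MseaParams-class] object.
#' @export
MseaParams <- function(quantileLevels = c(0.50, 0.60, 0.70, 0.80, 0.90,
                                          0.95, 0.975, 0.99, 0.995, 0.999),
                       kappa = 1, nPerm = 1000L, seed = 1L,
                       minGenes = 10L, maxGenes = 500L,
                       pMode = c("empirical", "gaussian"),
                       matchBins = TRUE) {
  new("MseaParams", quantileLevels = as.numeric(quantileLevels),
      kappa = as.numeric(kappa), nPerm = as.integer(nPerm),
      seed = as.integer(seed), minGenes = as.integer(minGenes),
      maxGenes = as.integer(maxGenes), pMode = match.arg(pMode),
      matchBins = isTRUE(matchBins))
}

#' Parameters for key driver analysis
#'
#' @slot depth neighborhood search depth (1..3; default 1).
#' @slot direction edge direction followed from the candidate hub: "out"
#'   (default; regulator to target), "in" or "both".
#' @slot minNbhd smallest neighborhood size tested (default 5).
#' @slot fdrMax BH FDR cutoff for calling a key driver (default 0.05).
#' @slot edgeMinStudies minimum per-edge study support; edges observed in
#'   fewer independent network studies are dropped before testing (default 1;
#'   2 for reported subnetworks).
#' @seealso [KdaParams()], [kdaTest()]
#' @export
setClass("KdaParams",
  representation(depth = "integer", direction = "character",
                 minNbhd = "integer", fdrMax = "numeric",
                 edgeMinStudies = "integer"))

setValidity("KdaParams", function(object) {
  if (object@depth < 1L || object@depth > 3L) return("depth must be in 1..3")
  if (!object@direction %in% c("out", "in", "both"))
    return("direction must be 'out', 'in' or 'both'")
  if (object@minNbhd < 1L) return("minNbhd must be >= 1")
  if (object@fdrMax <= 0 || object@fdrMax > 1)
    return("fdrMax must lie in (0, 1]")
  if (object@edgeMinStudies < 1L) return("edgeMinStudies must be >= 1")
  TRUE
})

#' Construct KDA parameters
#'
#' @param depth,direction,minNbhd,fdrMax,edgeMinStudies see
#'   [KdaParams-class].
#' @return A [KdaParams-class] object.
#' @export
KdaParams <- function(depth = 1L, direction = c("out", "in", "both"),
                      minNbhd = 5L, fdrMax = 0.05, edgeMinStudies = 1L) {
  new("KdaParams", depth = as.integer(depth),
      direction = match.arg(direction), minNbhd = as.integer(minNbhd),
      fdrMax = as.numeric(fdrMax), edgeMinStudies = as.integer(edgeMinStudies))
}

#' Configuration of the synthetic-data generator
#'
#' All generators are pure functions of (config, seed).  Defaults emulate a
#' desk-scale GWAS pathway study: 5000 markers, 500 genes with a
#' zero-truncated geometric number of markers per gene (mean 3), 100 gene
#' sets of 20 genes of which 10 are signal sets drawn from an overlapping
#' 100-gene signal pool, Beta(0.1, 1) signal p-values, LD in blocks of 5
#' markers at within-block r2 = 0.8, and a 1000-node directed network with
#' zero-truncated geometric out-degree (mean 30) and one planted key driver
#' wired to 10 targets of which 80\% are superset genes.
#'
#' @slot nMarkers,nGenes,markersPerGeneMean GWAS/mapping scale.
#' @slot nSets,setSize,nSignalSets,signalPoolSize,signalAlpha gene-set layer;
#'   signal markers are drawn from Beta(signalAlpha, 1).
#' @slot ldBlockSize,ldWithinR2 idealized equal-r2 LD blocks.
#' @slot netNodes,outDegreeMean,nPlantedKds,kdNbhdSize,kdOverlapFrac network
#'   layer.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  representation(nMarkers = "integer", nGenes = "integer",
                 markersPerGeneMean = "numeric",
                 nSets = "integer", setSize = "integer",
                 nSignalSets = "integer", signalPoolSize = "integer",
                 signalAlpha = "numeric",
                 ldBlockSize = "integer", ldWithinR2 = "numeric",
                 netNodes = "integer", outDegreeMean = "numeric",
                 nPlantedKds = "integer", kdNbhdSize = "integer",
                 kdOverlapFrac = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  pos <- c(nMarkers = object@nMarkers, nGenes = object@nGenes,
           nSets = object@nSets, setSize = object@setSize,
           ldBlockSize = object@ldBlockSize, netNodes = object@netNodes)
  if (any(pos < 1L))
    return(sprintf("%s must be positive", names(pos)[pos < 1L][1L]))
  if (object@nSignalSets < 0L || object@nSignalSets > object@nSets)
    return("nSignalSets must lie in 0..nSets")
  if (object@signalAlpha <= 0 || object@signalAlpha > 1)
    return("signalAlpha must lie in (0, 1]")
  if (object@markersPerGeneMean < 1) return("markersPerGeneMean must be >= 1")
  if (object@ldWithinR2 < 0 || object@ldWithinR2 > 1)
    return("ldWithinR2 must lie in [0, 1]")
  if (object@setSize > object@nGenes)
    return("setSize must not exceed nGenes")
  if (object@nSignalSets > 0L) {
    if (object@signalPoolSize < object@setSize)
      return("signalPoolSize must be >= setSize when signal sets are requested")
    if (object@signalPoolSize > object@nGenes)
      return("signalPoolSize must not exceed nGenes")
  }
  if (object@kdOverlapFrac < 0 || object@kdOverlapFrac > 1)
    return("kdOverlapFrac must lie in [0, 1]")
  if (object@kdNbhdSize > object@netNodes - 1L)
    return("kdNbhdSize must not exceed netNodes - 1")
  if (object@outDegreeMean < 1) return("outDegreeMean must be >= 1")
  TRUE
})

#' Construct a synthetic-data configuration
#'
#' @param nMarkers,nGenes,markersPerGeneMean,nSets,setSize,nSignalSets,
#'   signalPoolSize,signalAlpha,ldBlockSize,ldWithinR2,netNodes,
#'   outDegreeMean,nPlantedKds,kdNbhdSize,kdOverlapFrac,seed see
#'   [SimConfig-class].
#' @return A [SimConfig-class] object.
#' @export
SimConfig <- function(nMarkers = 5000L, nGenes = 500L,
                      markersPerGeneMean = 3, nSets = 100L, setSize = 20L,
                      nSignalSets = 10L, signalPoolSize = 100L,
                      signalAlpha = 0.1, ldBlockSize = 5L, ldWithinR2 = 0.8,
                      netNodes = 1000L, outDegreeMean = 30,
                      nPlantedKds = 1L, kdNbhdSize = 10L,
                      kdOverlapFrac = 0.8, seed = 1L) {
  new("SimConfig", nMarkers = as.integer(nMarkers),
      nGenes = as.integer(nGenes),
      markersPerGeneMean = as.numeric(markersPerGeneMean),
      nSets = as.integer(nSets), setSize = as.integer(setSize),
      nSignalSets = as.integer(nSignalSets),
      signalPoolSize = as.integer(signalPoolSize),
      signalAlpha = as.numeric(signalAlpha),
      ldBlockSize = as.integer(ldBlockSize),
      ldWithinR2 = as.numeric(ldWithinR2),
      netNodes = as.integer(netNodes),
      outDegreeMean = as.numeric(outDegreeMean),
      nPlantedKds = as.integer(nPlantedKds),
      kdNbhdSize = as.integer(kdNbhdSize),
      kdOverlapFrac = as.numeric(kdOverlapFrac), seed = as.integer(seed))
}
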