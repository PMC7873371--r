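## Seeded synthetic-data generator.  Every generator is a pure function of
## (config, seed): it seeds the RNG itself from cfg@seed plus a fixed
## per-stage offset (mapping +0, GWAS +1, network +2) so the stages draw from
## decorrelated streams while staying byte-reproducible.

.ztGeom <- function(n, mean) {
  ## zero-truncated geometric with the given mean (>= 1): 1 + Geom(1/mean)
  1L + rgeom(n, prob = 1 / mean)
}

#' Simulate a marker-gene map and gene-set collection with planted truth
#'
#' Each gene owns a zero-truncated-geometric number of markers (mean
#' `markersPerGeneMean`) drawn from the marker pool, so the map is
#' many-to-many.  `nSignalSets` signal sets are drawn (without replacement
#' within a set) from a shared `signalPoolSize`-gene signal pool, so signal
#' sets overlap one another -- giving the redundancy-merging stage something
#' real to merge; the remaining null sets are drawn from the non-signal genes
#' so the planted truth stays uncontaminated.  When `nSignalSets = 0` all
#' sets are drawn from the full gene universe.
#'
#' @param cfg a [SimConfig-class].
#' @return list with elements `map` ([MarkerGeneMap-class]), `sets`
#'   ([GeneSetList-class]) and `truth` (list: signalGenes, signalSets,
#'   signalMarkers, geneMarkers).
#' @export
simulateMappingAndSets <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  if (cfg@setSize > cfg@nGenes)
    stop("configuration error: setSize exceeds nGenes")
  set.seed(cfg@seed)
  genes <- sprintf("G%04d", seq_len(cfg@nGenes))
  markerPool <- sprintf("M%05d", seq_len(cfg@nMarkers))
  nPer <- pmin(.ztGeom(cfg@nGenes, cfg@markersPerGeneMean), cfg@nMarkers)
  geneMarkers <- lapply(nPer, function(k)
    markerPool[sample.int(cfg@nMarkers, k)])
  names(geneMarkers) <- genes

  if (cfg@nSignalSets > 0L) {
    signalPool <- sort(sample(genes, cfg@signalPoolSize))
    nullPool <- setdiff(genes, signalPool)
  } else {
    signalPool <- character(0)
    nullPool <- genes
  }
  if (cfg@nSets > cfg@nSignalSets && cfg@setSize > length(nullPool))
    stop("configuration error: not enough non-signal genes for null sets")
  setIdAll <- sprintf("SET%03d", seq_len(cfg@nSets))
  signalPos <- if (cfg@nSignalSets > 0L)
    sort(sample.int(cfg@nSets, cfg@nSignalSets)) else integer(0)
  sets <- vector("list", cfg@nSets)
  for (i in seq_len(cfg@nSets)) {
    pool <- if (i %in% signalPos) signalPool else nullPool
    sets[[i]] <- sort(pool[sample.int(length(pool), cfg@setSize)])
  }
  names(sets) <- setIdAll
  signalGenes <- sort(unique(unlist(sets[signalPos], use.names = FALSE)))
  signalMarkers <- sort(unique(unlist(geneMarkers[signalGenes],
                                      use.names = FALSE)))
  entries <- data.frame(
    marker_id = unlist(geneMarkers, use.names = FALSE),
    gene_id = rep(genes, nPer),
    source = "simulated", stringsAsFactors = FALSE)
  list(map = MarkerGeneMap(entries),
       sets = GeneSetList(sets,
                          source = ifelse(seq_len(cfg@nSets) %in% signalPos,
                                          "signal", "null")),
       truth = list(signalGenes = signalGenes,
                    signalSets = setIdAll[signalPos],
                    signalMarkers = signalMarkers,
                    geneMarkers = geneMarkers))
}

#' Simulate GWAS summary statistics with block LD
#'
#' Null markers draw p ~ Uniform(0, 1]; markers in `signalMarkers` draw
#' p ~ Beta(signalAlpha, 1) (alpha = 1 reduces to the null).  LD is idealized:
#' consecutive markers form blocks of `ldBlockSize` with within-block
#' r2 = `ldWithinR2` and zero across blocks (the pruner consumes only
#' pairwise r2, so block structure is all it needs).
#'
#' @param cfg a [SimConfig-class].
#' @param signalMarkers character vector of marker ids carrying signal
#'   (typically `truth$signalMarkers` from [simulateMappingAndSets()]).
#' @return list with elements `markers` (data.frame: marker_id, chrom, pos,
#'   pvalue, maf), `ld` ([LDTable-class]) and `truth` (list: signalMarkers).
#' @export
simulateGwas <- function(cfg, signalMarkers = character(0)) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed + 1L)
  n <- cfg@nMarkers
  ids <- sprintf("M%05d", seq_len(n))
  chrom <- as.character(rep_len(1:22, n))
  pos <- as.integer(seq_len(n) * 10000L)
  p <- runif(n)
  isSig <- ids %in% signalMarkers
  if (any(isSig)) p[isSig] <- rbeta(sum(isSig), cfg@signalAlpha, 1)
  p <- pmax(p, .Machine$double.xmin)   # keep strictly > 0
  maf <- runif(n, 0.01, 0.5)
  markers <- data.frame(marker_id = ids, chrom = chrom, pos = pos,
                        pvalue = p, maf = maf, stringsAsFactors = FALSE)
  block <- (seq_len(n) - 1L) %/% cfg@ldBlockSize
  pairs <- do.call(rbind, lapply(split(ids, block), function(b) {
    if (length(b) < 2) return(NULL)
    ix <- combn(length(b), 2)
    data.frame(marker_a = b[ix[1L, ]], marker_b = b[ix[2L, ]],
               r2 = cfg@ldWithinR2, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs))
    pairs <- data.frame(marker_a = character(0), marker_b = character(0),
                        r2 = numeric(0))
  rownames(pairs) <- NULL
  list(markers = markers, ld = LDTable(pairs),
       truth = list(signalMarkers = ids[isSig]))
}

#' Simulate a directed network with planted key drivers
#'
#' Background nodes get a zero-truncated geometric out-degree (mean
#' `outDegreeMean`) with uniformly sampled targets.  Each of the
#' `nPlantedKds` planted hubs is chosen outside the superset and wired to
#' exactly `kdNbhdSize` targets of which `round(kdOverlapFrac * kdNbhdSize)`
#' are superset genes -- and receives no background out-edges, so its
#' depth-1 out-neighborhood overlap is exactly that count.  Study support is
#' sampled uniformly from \{1, 2, 3\} for background edges and \{2, 3\} for
#' planted edges (so the planted subnetwork survives the two-study filter).
#'
#' @param cfg a [SimConfig-class].
#' @param supersetGenes character vector of superset gene ids (may be empty
#'   if `nPlantedKds = 0`).
#' @return list with elements `network` ([DirectedGeneNetwork-class]),
#'   `nodes` (all node ids, including any isolated ones) and `truth` (list:
#'   plantedKds, plantedTargets).
#' @export
simulateNetwork <- function(cfg, supersetGenes = character(0)) {
  stopifnot(is(cfg, "SimConfig"))
  if (cfg@kdNbhdSize > cfg@netNodes - 1L)
    stop("configuration error: kdNbhdSize exceeds netNodes - 1")
  set.seed(cfg@seed + 2L)
  nGeneNodes <- min(cfg@nGenes, cfg@netNodes)
  nodes <- c(sprintf("G%04d", seq_len(nGeneNodes)),
             if (cfg@netNodes > nGeneNodes)
               sprintf("N%04d", seq_len(cfg@netNodes - nGeneNodes)))
  S <- intersect(unique(normalizeGeneIds(supersetGenes)), nodes)
  nOver <- round(cfg@kdOverlapFrac * cfg@kdNbhdSize)
  if (cfg@nPlantedKds > 0L) {
    if (length(S) < nOver)
      stop("configuration error: superset too small for requested overlap")
    hubs <- sample(setdiff(nodes, S), cfg@nPlantedKds)
  } else hubs <- character(0)

  edges <- vector("list", length(nodes))
  names(edges) <- nodes
  bg <- setdiff(nodes, hubs)
  deg <- pmin(.ztGeom(length(bg), cfg@outDegreeMean), length(nodes) - 1L)
  for (i in seq_along(bg)) {
    v <- bg[i]
    tgt <- sample(setdiff(nodes, v), deg[i])
    edges[[v]] <- data.frame(tail = v, head = tgt,
                             weight = 1,
                             n_studies = sample(1:3, deg[i], replace = TRUE),
                             stringsAsFactors = FALSE)
  }
  plantedTargets <- list()
  for (h in hubs) {
    over <- sample(S, nOver)
    rest <- sample(setdiff(nodes, c(S, h, hubs)), cfg@kdNbhdSize - nOver)
    tgt <- c(over, rest)
    plantedTargets[[h]] <- sort(tgt)
    edges[[h]] <- data.frame(tail = h, head = tgt, weight = 1,
                             n_studies = sample(2:3, length(tgt),
                                                replace = TRUE),
                             stringsAsFactors = FALSE)
  }
  e <- do.call(rbind, edges[!vapply(edges, is.null, TRUE)])
  rownames(e) <- NULL
  list(network = DirectedGeneNetwork(e), nodes = nodes,
       truth = list(plantedKds = sort(hubs), plantedTargets = plantedTargets))
}

#' Simulate a complete study
#'
#' Orchestrates the three generators in dependency order: the marker-gene map
#' and gene sets first (signal is planted at the gene level, so the map must
#' exist before p-values are drawn), then the GWAS p-values with the signal
#' markers, then the network with the signal genes as the planted superset.
#'
#' @param cfg a [SimConfig-class].
#' @return list with elements markers, ld, map, sets, network, nodes and
#'   truth (the union of the per-stage truth lists).
#' @export
simulateStudy <- function(cfg = SimConfig()) {
  ms <- simulateMappingAndSets(cfg)
  gw <- simulateGwas(cfg, signalMarkers = ms$truth$signalMarkers)
  nw <- simulateNetwork(cfg, supersetGenes = ms$truth$signalGenes)
  list(markers = gw$markers, ld = gw$ld, map = ms$map, sets = ms$sets,
       network = nw$network, nodes = nw$nodes,
       truth = c(ms$truth, nw$truth))
}

#' Write a simulated study to disk in the package's exchange formats
#'
#' Writes gwas.tsv, ld.tsv, map.tsv, sets.gmt, network.tsv and a truth.json
#' sidecar (schema: signalGenes, signalSets, signalMarkers, plantedKds,
#' plantedTargets) sufficient to score recovery without re-reading the
#' config.
#'
#' @param study list as returned by [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulatedStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGwas(study$markers, file.path(dir, "gwas.tsv"))
  writeLdTable(study$ld, file.path(dir, "ld.tsv"))
  writeMarkerGeneMap(study$map, file.path(dir, "map.tsv"))
  writeGeneSetsGmt(study$sets, file.path(dir, "sets.gmt"))
  writeNetwork(study$network, file.path(dir, "network.tsv"))
  truth <- study$truth
  truth$geneMarkers <- NULL   # derivable from map.tsv
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}
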