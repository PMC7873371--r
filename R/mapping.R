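## Marker-to-gene mapping: chromosomal distance, tissue eQTL and regulatory
## annotation evidence, plus the nine canonical mapping configurations.

#' The nine canonical mapping configurations
#'
#' Enumerates the mapping configurations used throughout the workflow: one
#' per tissue eQTL source, the union of all tissue eQTL sources ("eSNP all"),
#' chromosomal distance, regulatory annotation ("regulome"), and the union of
#' everything ("combined").
#'
#' @param tissues character vector of tissue labels with eQTL evidence
#'   (default adipose, blood, brain, haec, liver).
#' @return named list of configurations, each a list with elements `name` and
#'   `sources` (the source tags to union).
#' @examples
#' names(mappingConfigs())
#' @export
mappingConfigs <- function(tissues = c("adipose", "blood", "brain",
                                       "haec", "liver")) {
  eTags <- paste0("eSNP_", tissues)
  cfgs <- lapply(seq_along(tissues), function(i)
    list(name = paste0("eSNP ", tissues[i]), sources = eTags[i]))
  names(cfgs) <- paste0("eSNP_", tissues)
  cfgs$eSNP_all <- list(name = "eSNP all", sources = eTags)
  cfgs$distance <- list(name = "Distance", sources = "distance")
  cfgs$regulome <- list(name = "Regulome", sources = "regulome")
  cfgs$combined <- list(name = "Combined",
                        sources = c(eTags, "distance", "regulome"))
  cfgs
}

#' Map markers to genes by chromosomal distance
#'
#' A marker is mapped to a gene if it lies within `windowBp` of the gene
#' region, i.e. its position falls in `[start - windowBp, end + windowBp]`
#' (inclusive at both boundaries) on the same chromosome.  Markers lacking a
#' position are skipped, with the count reported via [message()] and the
#' `"n_skipped"` attribute.
#'
#' @param markers data.frame as from [readGwas()]; needs chrom and pos.
#' @param annotations data.frame as from [readGeneAnnotation()].
#' @param windowBp mapping window in base pairs (default 50,000, the
#'   conventional +/- 50 kb gene boundary used in GWAS).
#' @return A [MarkerGeneMap-class] with source tag "distance".
#' @export
mapByDistance <- function(markers, annotations, windowBp = 50000L) {
  stopifnot(is.data.frame(markers), is.data.frame(annotations),
            windowBp >= 0)
  hasPos <- c("chrom", "pos") %in% names(markers)
  if (!all(hasPos)) {
    if (nrow(markers) > 0)
      stop("markers need 'chrom' and 'pos' columns for distance mapping")
    markers$chrom <- character(0); markers$pos <- integer(0)
  }
  usable <- !is.na(markers$pos) & !is.na(markers$chrom)
  nSkipped <- sum(!usable)
  if (nSkipped > 0)
    message(sprintf("mapByDistance: skipped %d marker(s) without position",
                    nSkipped))
  m <- markers[usable, , drop = FALSE]
  out <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    lo <- annotations$start[i] - windowBp
    hi <- annotations$end[i] + windowBp
    hit <- m$chrom == annotations$chrom[i] & m$pos >= lo & m$pos <= hi
    if (any(hit))
      out[[i]] <- data.frame(marker_id = m$marker_id[hit],
                             gene_id = annotations$gene_id[i],
                             source = "distance",
                             stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  entries <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(marker_id = character(0), gene_id = character(0),
               source = character(0))
  res <- MarkerGeneMap(entries)
  attr(res, "n_skipped") <- nSkipped
  res
}

#' Map markers to genes via eQTL evidence
#'
#' Retains expression-SNP (eSNP) rows with eQTL FDR below `fdrMax` (default
#' 10\%).  The cis flag is TRUE when the marker lies within 1 Mb of the gene
#' region (|distance_bp| <= 1,000,000), FALSE beyond, and NA when the
#' distance is unknown; both cis- and trans-eSNPs are kept.  The source tag
#' is `"eSNP_<tissue>"`.
#'
#' @param eqtl data.frame with columns marker_id, gene_id, tissue, fdr and
#'   optionally distance_bp.
#' @param fdrMax eQTL FDR cutoff (default 0.10).
#' @param cisMaxBp cis/trans boundary in base pairs (default 1e6; <= is cis).
#' @return A [MarkerGeneMap-class] with cis and eqtl_fdr columns.
#' @export
mapByEqtl <- function(eqtl, fdrMax = 0.10, cisMaxBp = 1000000L) {
  stopifnot(is.data.frame(eqtl))
  if (nrow(eqtl) == 0)
    return(MarkerGeneMap(data.frame(marker_id = character(0),
                                    gene_id = character(0),
                                    source = character(0))))
  need <- c("marker_id", "gene_id", "tissue", "fdr")
  .requireCols(names(eqtl), need, "eqtl table")
  f <- as.numeric(eqtl$fdr)
  if (any(is.na(f) | f < 0 | f > 1))
    stop("eqtl fdr must lie in [0, 1]")
  keep <- f < fdrMax
  e <- eqtl[keep, , drop = FALSE]
  cis <- if ("distance_bp" %in% names(e))
    abs(as.numeric(e$distance_bp)) <= cisMaxBp else rep(NA, nrow(e))
  MarkerGeneMap(data.frame(marker_id = as.character(e$marker_id),
                           gene_id = as.character(e$gene_id),
                           source = paste0("eSNP_", as.character(e$tissue)),
                           cis = as.logical(cis),
                           eqtl_fdr = as.numeric(e$fdr),
                           stringsAsFactors = FALSE))
}

#' Map markers to genes via regulatory-element annotation
#'
#' Accepts a pre-paired table of regulatory markers and their target genes
#' (the pairing rule -- nearest gene, annotated element target, ... -- is the
#' data provider's choice).  Duplicate rows collapse to one entry.
#'
#' @param regulome data.frame with columns marker_id and gene_id.
#' @return A [MarkerGeneMap-class] with source tag "regulome".
#' @export
mapByRegulome <- function(regulome) {
  stopifnot(is.data.frame(regulome))
  if (nrow(regulome) == 0)
    return(MarkerGeneMap(data.frame(marker_id = character(0),
                                    gene_id = character(0),
                                    source = character(0))))
  .requireCols(names(regulome), c("marker_id", "gene_id"), "regulome table")
  MarkerGeneMap(data.frame(marker_id = as.character(regulome$marker_id),
                           gene_id = as.character(regulome$gene_id),
                           source = "regulome", stringsAsFactors = FALSE))
}

#' Combine mapping sources under a named configuration
#'
#' Set-union of the entries whose source tag is named by the configuration.
#' A (marker, gene) pair supported by k of the named sources keeps its k
#' source rows (no winner-takes-all pruning; enrichment testing operates on
#' the full many-to-many map via [mapPairs()]).  The operation is idempotent
#' and commutative over the input maps.
#'
#' @param maps list of [MarkerGeneMap-class] objects (or a single one).
#' @param config one element of [mappingConfigs()]: a list with `name` and
#'   `sources`.
#' @return A [MarkerGeneMap-class] restricted to the configured sources.
#' @export
combineMappings <- function(maps, config) {
  if (is(maps, "MarkerGeneMap")) maps <- list(maps)
  stopifnot(is.list(maps), all(vapply(maps, is, TRUE, "MarkerGeneMap")))
  if (is.null(config$sources) || length(config$sources) == 0)
    stop("configuration error: config$sources must be non-empty")
  all <- do.call(rbind, lapply(maps, mapEntries))
  if (is.null(all))
    all <- data.frame(marker_id = character(0), gene_id = character(0),
                      source = character(0))
  unknown <- setdiff(config$sources, unique(all$source))
  if (length(unknown) > 0)
    stop(sprintf("configuration error: unknown source tag(s): %s",
                 paste(unknown, collapse = ", ")))
  MarkerGeneMap(all[all$source %in% config$sources,
                    c("marker_id", "gene_id", "source"), drop = FALSE])
}

#' Audit a mapping against a GWAS marker table
#'
#' Flags map entries whose marker does not appear in the GWAS study.
#'
#' @param map a [MarkerGeneMap-class].
#' @param markers data.frame as from [readGwas()].
#' @return character vector of marker ids present in the map but absent from
#'   the GWAS table (empty when fully covered).
#' @export
unmappedInGwas <- function(map, markers) {
  stopifnot(is(map, "MarkerGeneMap"))
  setdiff(unique(mapEntries(map)$marker_id), markers$marker_id)
}
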