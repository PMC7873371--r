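## Readers/writers for the tab-delimited exchange formats.  All writers emit
## a canonical form: fixed column order, tab separator, "NA" for missing,
## numbers via %.10g (lowercase scientific for small values), so that
## write(read(f)) reproduces a canonical file byte-for-byte.

.fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", as.numeric(x)))

.writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col)) .fmtNum(col)
      else ifelse(is.na(col), "NA", as.character(col))
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

.readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = "character", check.names = FALSE,
             na.strings = "NA", quote = "")
}

.numCol <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0)
    stop(sprintf("%s: non-numeric %s at data row %d ('%s')",
                 path, what, bad[1L], x[bad[1L]]))
  out
}

.requireCols <- function(found, need, path) {
  miss <- setdiff(need, found)
  if (length(miss) > 0)
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(miss, collapse = ", ")))
}

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited table of per-marker association results with header
#' `marker_id[, chrom, pos,] pvalue[, maf]`.  Markers with minor allele
#' frequency below `mafMin` are removed when a `maf` column is present
#' (the source study excluded MAF < 1\%); the number of rows dropped is
#' reported via [message()] and recorded in the `"n_dropped_maf"` attribute.
#' Row order is preserved.
#'
#' A p-value of exactly 0 (or outside (0, 1]) is a validation error, not a
#' clamp: downstream -log10 transforms must stay finite, so the user must
#' pre-clamp deliberately.
#'
#' @param path path to the tab-delimited file.
#' @param mafMin minimum minor allele frequency retained (default 0.01).
#' @return data.frame with columns marker_id, pvalue and, when present in the
#'   file, chrom, pos, maf.
#' @examples
#' f <- tempfile()
#' writeLines(c("marker_id\tpvalue\tmaf", "rs1\t1e-8\t0.30",
#'              "rs2\t0.5\t0.005"), f)
#' readGwas(f)   # rs2 dropped: maf < 1%
#' @export
readGwas <- function(path, mafMin = 0.01) {
  raw <- .readTsv(path)
  .requireCols(names(raw), c("marker_id", "pvalue"), path)
  out <- data.frame(marker_id = as.character(raw$marker_id),
                    stringsAsFactors = FALSE)
  if ("chrom" %in% names(raw)) out$chrom <- as.character(raw$chrom)
  if ("pos" %in% names(raw))
    out$pos <- as.integer(.numCol(raw$pos, "pos", path))
  out$pvalue <- .numCol(raw$pvalue, "pvalue", path)
  if ("maf" %in% names(raw)) out$maf <- .numCol(raw$maf, "maf", path)
  if (anyDuplicated(out$marker_id))
    stop(sprintf("%s: duplicate marker_id '%s'", path,
                 out$marker_id[duplicated(out$marker_id)][1L]))
  bad <- which(is.na(out$pvalue) | out$pvalue <= 0 | out$pvalue > 1)
  if (length(bad) > 0)
    stop(sprintf("%s: invalid pvalue for marker '%s' (must lie in (0, 1])",
                 path, out$marker_id[bad[1L]]))
  if (!is.null(out$maf) && any(!is.na(out$maf) & out$maf > 0.5))
    stop(sprintf("%s: maf > 0.5 for marker '%s'", path,
                 out$marker_id[which(out$maf > 0.5)[1L]]))
  nDropped <- 0L
  if (!is.null(out$maf)) {
    keep <- is.na(out$maf) | out$maf >= mafMin
    nDropped <- sum(!keep)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  if (nDropped > 0)
    message(sprintf("readGwas: dropped %d marker(s) with maf < %g",
                    nDropped, mafMin))
  attr(out, "n_dropped_maf") <- nDropped
  out
}

#' Write GWAS summary statistics in canonical form
#'
#' @param markers data.frame as returned by [readGwas()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGwas <- function(markers, path) {
  cols <- intersect(c("marker_id", "chrom", "pos", "pvalue", "maf"),
                    names(markers))
  .writeTsv(markers[, cols, drop = FALSE], path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `set_id TAB description TAB gene
#' TAB gene ...`.  Duplicate genes within a line are deduplicated; a line
#' with fewer than three fields is a format error reporting the line number;
#' duplicate set ids are a validation error.  No size filtering happens here:
#' size bounds are enforced (as skips, with reasons) by [runMsea()].
#'
#' @param path path to the GMT file.
#' @param source provenance label stored on every set (default "gmt").
#' @return A [GeneSetList-class].
#' @export
readGeneSetsGmt <- function(path, source = "gmt") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(GeneSetList(setNames(list(), character(0)),
                       description = character(0), source = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop(sprintf("%s: GMT line %d has %d field(s); need set_id, description ",
                 path, which(nf < 3)[1L], nf[nf < 3][1L]),
         "and at least one gene")
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate set id '%s'", path,
                 ids[duplicated(ids)][1L]))
  desc <- vapply(parts, `[[`, "", 2L)
  genes <- lapply(parts, function(p) {
    g <- p[-(1:2)]
    g[nzchar(g)]
  })
  names(genes) <- ids
  GeneSetList(genes, description = desc,
              source = rep(source, length(ids)))
}

#' Write a GeneSetList as GMT
#'
#' @param gsl a [GeneSetList-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneSetsGmt <- function(gsl, path) {
  stopifnot(is(gsl, "GeneSetList"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nSets(gsl))) {
    writeLines(paste(c(gsl@setId[i], gsl@description[i], gsl@genes[[i]]),
                     collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Build a positive-control gene set from trait-associated loci
#'
#' Collects the unique genes whose reported association p-value passes the
#' genome-wide threshold (default P < 5.0e-8), mirroring the construction of
#' positive-control pathways from known trait-associated loci.  An empty
#' result is an error: a positive control must be non-empty to be usable.
#'
#' @param catalog data.frame with columns gene_id and p.
#' @param pThreshold significance threshold (default 5e-8).
#' @param setId identifier for the resulting set.
#' @param description free-text description.
#' @return A one-set [GeneSetList-class] with source "positive_control".
#' @export
buildPositiveControl <- function(catalog, pThreshold = 5e-8,
                                 setId = "positive_control",
                                 description = "known trait-associated loci") {
  stopifnot(is.data.frame(catalog), all(c("gene_id", "p") %in% names(catalog)))
  genes <- unique(normalizeGeneIds(catalog$gene_id[catalog$p < pThreshold]))
  if (length(genes) == 0)
    stop(sprintf("no gene passes p < %g: positive control would be empty",
                 pThreshold))
  GeneSetList(setNames(list(genes), setId), description = description,
              source = "positive_control")
}

#' Read a directed network edge list
#'
#' Tab-delimited `tail head [weight] [n_studies]` (weight defaults to 1,
#' n_studies to 1).  Self-loops are removed and counted; edges supported by
#' fewer than `minStudies` independent network studies are dropped (the
#' reported subnetworks keep only edges present in at least two studies).
#'
#' @param path path to the edge list.
#' @param minStudies minimum per-edge study support retained (default 1).
#' @return A [DirectedGeneNetwork-class].
#' @export
readNetwork <- function(path, minStudies = 1L) {
  raw <- .readTsv(path)
  .requireCols(names(raw), c("tail", "head"), path)
  e <- data.frame(tail = as.character(raw$tail),
                  head = as.character(raw$head),
                  stringsAsFactors = FALSE)
  e$weight <- if ("weight" %in% names(raw))
    .numCol(raw$weight, "weight", path) else rep(1, nrow(e))
  e$n_studies <- if ("n_studies" %in% names(raw))
    as.integer(.numCol(raw$n_studies, "n_studies", path)) else rep(1L, nrow(e))
  self <- e$tail == e$head
  if (any(self))
    message(sprintf("readNetwork: removed %d self-loop(s)", sum(self)))
  e <- e[!self, , drop = FALSE]
  lowSupport <- e$n_studies < minStudies
  if (any(lowSupport))
    message(sprintf("readNetwork: removed %d edge(s) with n_studies < %d",
                    sum(lowSupport), minStudies))
  e <- e[!lowSupport, , drop = FALSE]
  DirectedGeneNetwork(e)
}

#' Write a directed network edge list in canonical form
#'
#' @param net a [DirectedGeneNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path) {
  stopifnot(is(net, "DirectedGeneNetwork"))
  .writeTsv(networkEdges(net), path)
}

#' Read a marker-to-gene mapping table
#'
#' Tab-delimited `marker_id gene_id source [cis] [eqtl_fdr]`.
#'
#' @param path path to the mapping table.
#' @return A [MarkerGeneMap-class].
#' @export
readMarkerGeneMap <- function(path) {
  raw <- .readTsv(path)
  .requireCols(names(raw), c("marker_id", "gene_id", "source"), path)
  e <- data.frame(marker_id = as.character(raw$marker_id),
                  gene_id = as.character(raw$gene_id),
                  source = as.character(raw$source),
                  stringsAsFactors = FALSE)
  if ("cis" %in% names(raw)) e$cis <- as.logical(raw$cis)
  if ("eqtl_fdr" %in% names(raw))
    e$eqtl_fdr <- .numCol(raw$eqtl_fdr, "eqtl_fdr", path)
  MarkerGeneMap(e)
}

#' Write a marker-to-gene mapping table in canonical form
#'
#' @param map a [MarkerGeneMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMarkerGeneMap <- function(map, path) {
  stopifnot(is(map, "MarkerGeneMap"))
  e <- mapEntries(map)
  cols <- intersect(c("marker_id", "gene_id", "source", "cis", "eqtl_fdr"),
                    names(e))
  .writeTsv(e[, cols, drop = FALSE], path)
}

#' Read a pairwise LD table
#'
#' Tab-delimited `marker_a marker_b r2`.  Lookup is symmetric; a pair absent
#' from the table is treated as r2 = 0.
#'
#' @param path path to the LD table.
#' @return An [LDTable-class].
#' @export
readLdTable <- function(path) {
  raw <- .readTsv(path)
  .requireCols(names(raw), c("marker_a", "marker_b", "r2"), path)
  LDTable(data.frame(marker_a = as.character(raw$marker_a),
                     marker_b = as.character(raw$marker_b),
                     r2 = .numCol(raw$r2, "r2", path),
                     stringsAsFactors = FALSE))
}

#' Write an LD table in canonical form
#'
#' @param ld an [LDTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLdTable <- function(ld, path) {
  stopifnot(is(ld, "LDTable"))
  .writeTsv(ldPairs(ld), path)
}

#' Symmetric LD lookup
#'
#' @param ld an [LDTable-class].
#' @param a,b marker identifiers.
#' @return r-squared between `a` and `b`; 0 when the pair is absent.
#' @export
r2Between <- function(ld, a, b) {
  stopifnot(is(ld, "LDTable"))
  p <- ld@pairs
  hit <- (p$marker_a == a & p$marker_b == b) |
         (p$marker_a == b & p$marker_b == a)
  if (!any(hit)) return(0)
  max(p$r2[hit])
}

#' Read gene annotations (1-based inclusive coordinates)
#'
#' Tab-delimited `gene_id chrom start end`.  Coordinates are 1-based and
#' inclusive at both ends, matching the dominant GWAS/annotation convention.
#'
#' @param path path to the annotation table.
#' @return data.frame with columns gene_id, chrom, start, end.
#' @export
readGeneAnnotation <- function(path) {
  raw <- .readTsv(path)
  .requireCols(names(raw), c("gene_id", "chrom", "start", "end"), path)
  out <- data.frame(gene_id = normalizeGeneIds(raw$gene_id),
                    chrom = as.character(raw$chrom),
                    start = as.integer(.numCol(raw$start, "start", path)),
                    end = as.integer(.numCol(raw$end, "end", path)),
                    stringsAsFactors = FALSE)
  bad <- which(out$start > out$end)
  if (length(bad) > 0)
    stop(sprintf("%s: start > end for gene '%s'", path,
                 out$gene_id[bad[1L]]))
  out
}
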