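# Shared fixtures and independent brute-force oracles.

writeTmpLines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# Literal Benjamini-Hochberg step-up: q_i = min over p_(j) >= p_(i) of
# p_(j) * m / rank(j), clipped at 1.  Kept deliberately naive.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[o] >= p[i] - 1e-15)
    q[i] <- min(1, min(p[o][js] * m / js))
  }
  q
}

# Hypergeometric upper tail P[X >= k] by direct summation over choose().
bruteHyperTail <- function(k, nQuery, nTerm, nUniverse) {
  ks <- max(0, k):min(nQuery, nTerm)
  if (k > min(nQuery, nTerm)) return(0)
  sum(choose(nTerm, ks) * choose(nUniverse - nTerm, nQuery - ks) /
        choose(nUniverse, nQuery))
}

# Tiny hand-built gene-marker index: 12 markers across 7 genes, two of the
# genes loaded with small p-values.
tinyIndex <- function() {
  markers <- data.frame(
    marker_id = sprintf("m%02d", 1:12),
    pvalue = c(1e-4, 2e-4, 5e-4, 0.02, 0.10, 0.25, 0.40, 0.55, 0.70,
               0.85, 0.92, 0.99))
  map <- MarkerGeneMap(data.frame(
    marker_id = c("m01", "m02", "m03", "m04", "m05", "m06", "m07",
                  "m08", "m09", "m10", "m11", "m12", "m01", "m05"),
    gene_id = c("gA", "gA", "gB", "gB", "gC", "gC", "gD", "gD", "gE",
                "gE", "gF", "gG", "gG", "gF"),
    source = "fix"))
  list(index = buildGeneMarkerIndex(map, markers), markers = markers,
       map = map)
}

# Random GeneSetList over a lettered gene pool.
randomGeneSetList <- function(nSets, poolSize = 40, minSize = 4,
                              maxSize = 12) {
  pool <- sprintf("g%02d", seq_len(poolSize))
  sets <- lapply(seq_len(nSets), function(i)
    sample(pool, sample(minSize:maxSize, 1)))
  names(sets) <- sprintf("S%02d", seq_len(nSets))
  GeneSetList(sets)
}

# Exhaustive DFS over every legal merge sequence (any pair with overlap
# coefficient >= rho may merge next); returns the distinct terminal
# partitions, each canonicalized as a sorted list of sorted member-id
# vectors.
allMergePartitions <- function(genes, rho) {
  canon <- function(clusters) {
    parts <- lapply(clusters, function(cl) sort(cl$ids))
    parts[order(vapply(parts, paste, "", collapse = "|"))]
  }
  results <- new.env(parent = emptyenv())
  recurse <- function(clusters) {
    n <- length(clusters)
    mergeable <- list()
    if (n >= 2) {
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        co <- length(intersect(clusters[[i]]$genes, clusters[[j]]$genes)) /
          min(length(clusters[[i]]$genes), length(clusters[[j]]$genes))
        if (co >= rho) mergeable[[length(mergeable) + 1L]] <- c(i, j)
      }
    }
    if (length(mergeable) == 0) {
      key <- paste(vapply(canon(clusters), paste, "", collapse = "|"),
                   collapse = "||")
      assign(key, canon(clusters), envir = results)
      return(invisible(NULL))
    }
    for (pr in mergeable) {
      merged <- list(ids = c(clusters[[pr[1]]]$ids, clusters[[pr[2]]]$ids),
                     genes = union(clusters[[pr[1]]]$genes,
                                   clusters[[pr[2]]]$genes))
      recurse(c(clusters[-pr], list(merged)))
    }
  }
  recurse(lapply(names(genes), function(id)
    list(ids = id, genes = unique(toupper(genes[[id]])))))
  as.list(results)
}

# Exact best maximal independent set of the high-LD conflict graph: among
# all maximal independent sets, the one whose sorted p-value sequence is
# lexicographically smallest (ties by marker id).  n <= 12 only.
bruteForcePrune <- function(markers, ldDf, r2Max) {
  ids <- markers$marker_id
  n <- length(ids)
  conflict <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(ldDf))) {
    if (ldDf$r2[r] >= r2Max) {
      conflict[ldDf$marker_a[r], ldDf$marker_b[r]] <- TRUE
      conflict[ldDf$marker_b[r], ldDf$marker_a[r]] <- TRUE
    }
  }
  ord <- order(markers$pvalue, markers$marker_id)
  rank <- integer(n); rank[ord] <- seq_len(n)
  best <- NULL; bestKey <- NULL
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(sel) == 0) next
    if (any(conflict[sel, sel, drop = FALSE])) next
    # maximal: no excluded marker can be added
    addable <- vapply(setdiff(seq_len(n), sel), function(e)
      !any(conflict[e, sel]), TRUE)
    if (length(addable) > 0 && any(addable)) next
    key <- paste(sprintf("%03d", sort(rank[sel])), collapse = ",")
    if (is.null(bestKey) || key < bestKey) {
      bestKey <- key
      best <- sel
    }
  }
  ids[best][order(rank[best])]
}
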