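test_that("computeCutoffs returns background quantiles of -log10(p)", {
  p <- seq(0.1, 1.0, by = 0.1)
  expect_equal(computeCutoffs(p, 0.5), stats::median(-log10(p)))
  expect_equal(computeCutoffs(rep(0.2, 10), c(0.5, 0.9)),
               rep(-log10(0.2), 2))
  thr <- computeCutoffs(runif(50), c(0.5, 0.9))
  expect_lte(thr[1], thr[2])
  expect_error(computeCutoffs(runif(9), 0.5), "at least 10")
})

test_that("the enrichment statistic matches hand arithmetic", {
  expect_equal(mseaStatistic(4, 4, kappa = 1), 0)
  expect_equal(mseaStatistic(9, 4, kappa = 1), 5 / sqrt(5))
  expect_equal(mseaStatistic(c(9, 3), c(4, 1), kappa = 1),
               5 / sqrt(5) + 2 / sqrt(2))
  expect_error(mseaStatistic(c(1, 2), 1), "equal length")
  expect_error(mseaStatistic(-1, 1), "non-negative")
})

test_that("bhFdr reproduces the step-up procedure", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_equal(bhFdr(numeric(0)), numeric(0))
  expect_error(bhFdr(c(0.5, 0)), "\\(0, 1\\]")

  set.seed(8)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhFdr(p), bruteForceBH(p))
  }
})

test_that("two-dataset intersection reports the product FDR bound", {
  a <- data.frame(set_id = c("S1", "S2", "S3"), fdr = c(0.05, 0.5, 0.01))
  b <- data.frame(set_id = c("S1", "S2", "S3"), fdr = c(0.02, 0.02, 0.20))
  res <- combineTwoDatasets(a, b, fdrMaxA = 0.10)
  expect_equal(res$combinedFdrBound, 0.01)   # 10% x 10% = 1%
  expect_equal(res$setIds, "S1")             # S3 significant in A only

  res2 <- combineTwoDatasets(a, b, fdrMaxA = 0.10, fdrMaxB = 0.25)
  expect_equal(res2$combinedFdrBound, 0.025) # 10% x 25% = 2.5%
  expect_setequal(res2$setIds, c("S1", "S3"))
})

test_that("exhaustive Monte Carlo equals full enumeration on a tiny universe", {
  fx <- tinyIndex()
  params <- MseaParams(minGenes = 1L, seed = 5L)
  res <- mseaTest(c("gA", "gB", "gC"), fx$index, params, exhaustive = TRUE)

  # independent oracle: recompute by literal enumeration
  mlp <- -log10(fx$markers$pvalue)
  thr <- quantile(mlp, params@quantileLevels, names = FALSE)
  geneMarkers <- lapply(split(mapPairs(fx$map)$marker_id,
                              mapPairs(fx$map)$gene_id), unique)
  xFor <- function(genes) {
    u <- unique(unlist(geneMarkers[genes]))
    mu <- mlp[match(u, fx$markers$marker_id)]
    O <- vapply(thr, function(t) sum(mu >= t), 0)
    E <- length(u) * (1 - params@quantileLevels)
    sum((O - E) / sqrt(E + 1))
  }
  universe <- names(geneMarkers)
  expect_length(universe, 7L)
  combos <- combn(universe, 3)
  xAll <- apply(combos, 2, xFor)
  xObs <- xFor(c("GA", "GB", "GC"))
  expect_equal(res$X, xObs)
  expect_equal(res$pvalue, mean(xAll >= xObs))
  expect_equal(ncol(combos), 35L)
})

test_that("a set equal to the whole universe cannot be enriched", {
  fx <- tinyIndex()
  res <- mseaTest(c("gA", "gB", "gC", "gD", "gE", "gF", "gG"), fx$index,
                  MseaParams(minGenes = 1L, nPerm = 200L))
  expect_equal(res$pvalue, 1)          # every permutation draws the same set

  # on a realistic background, X for set = universe stays near 0 (only
  # quantile discreteness keeps it from vanishing)
  cfg <- SimConfig(seed = 7L, nMarkers = 2000L, nGenes = 150L, nSets = 5L,
                   setSize = 10L, nSignalSets = 0L, nPlantedKds = 0L)
  ms <- simulateMappingAndSets(cfg)
  gw <- simulateGwas(cfg)
  idx <- buildGeneMarkerIndex(ms$map, gw$markers)
  resAll <- mseaTest(sprintf("G%04d", 1:150), idx,
                     MseaParams(minGenes = 1L, nPerm = 100L,
                                maxGenes = 1000L))
  expect_equal(resAll$pvalue, 1)
  expect_lt(abs(resAll$X), 2)
})

test_that("sets outside the size bounds are skipped with a reason", {
  fx <- tinyIndex()
  small <- mseaTest("gA", fx$index, MseaParams(minGenes = 2L))
  expect_match(small$status, "too_few")
  unmapped <- mseaTest(c("nope1", "nope2"), fx$index,
                       MseaParams(minGenes = 1L))
  expect_match(unmapped$status, "no_mapped_genes")
  big <- mseaTest(c("gA", "gB", "gC"), fx$index,
                  MseaParams(minGenes = 1L, maxGenes = 2L))
  expect_match(big$status, "too_many")
})

test_that("runMsea is reproducible bit-for-bit under a fixed seed", {
  cfg <- SimConfig(seed = 7L, nMarkers = 600L, nGenes = 80L, nSets = 12L,
                   setSize = 8L, nSignalSets = 2L, signalPoolSize = 20L,
                   nPlantedKds = 0L)
  ms <- simulateMappingAndSets(cfg)
  gw <- simulateGwas(cfg, ms$truth$signalMarkers)
  idx <- buildGeneMarkerIndex(ms$map, gw$markers)
  params <- MseaParams(nPerm = 150L, seed = 42L, minGenes = 3L)
  r1 <- runMsea(ms$sets, idx, params)
  r2 <- runMsea(ms$sets, idx, params)
  expect_identical(r1, r2)
  expect_true(all(r1$status %in%
                    c("ok", "skipped:too_few_mapped_genes",
                      "skipped:no_mapped_genes")))
  # BH applied over tested sets only, input order preserved
  ok <- r1$status == "ok"
  expect_equal(r1$fdr[ok], bhFdr(r1$pvalue[ok]))
})

test_that("stronger planted signal never weakens the median statistic", {
  medX <- function(alpha) {
    xs <- vapply(1:3, function(s) {
      cfg <- SimConfig(seed = 200L + s, nMarkers = 800L, nGenes = 100L,
                       nSets = 10L, setSize = 10L, nSignalSets = 2L,
                       signalPoolSize = 25L, signalAlpha = alpha,
                       nPlantedKds = 0L)
      ms <- simulateMappingAndSets(cfg)
      gw <- simulateGwas(cfg, ms$truth$signalMarkers)
      idx <- buildGeneMarkerIndex(ms$map, gw$markers)
      sid <- ms$truth$signalSets[1]
      mseaTest(geneSets(ms$sets)[[sid]], idx,
               MseaParams(nPerm = 100L, seed = 1L, minGenes = 3L))$X
    }, 0)
    stats::median(xs)
  }
  expect_gte(medX(0.1), medX(0.5))
  expect_gte(medX(0.5), medX(1.0) - 1e-9)
})

test_that("gaussian p-mode gives a tail probability consistent with empirical", {
  fx <- tinyIndex()
  pe <- mseaTest(c("gA", "gB", "gC"), fx$index,
                 MseaParams(minGenes = 1L, nPerm = 400L, seed = 2L))
  pg <- mseaTest(c("gA", "gB", "gC"), fx$index,
                 MseaParams(minGenes = 1L, nPerm = 400L, seed = 2L,
                            pMode = "gaussian"))
  expect_gt(pg$pvalue, 0)
  expect_lte(pg$pvalue, 1)
  expect_equal(pe$X, pg$X)
})
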