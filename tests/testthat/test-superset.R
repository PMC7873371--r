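test_that("overlap coefficient handles nesting, disjointness and errors", {
  expect_equal(overlapCoefficient(letters[1:5], letters[1:5]), 1)
  expect_equal(overlapCoefficient(letters[1:5], letters[6:10]), 0)
  expect_equal(overlapCoefficient(sprintf("x%02d", 1:10),
                                  sprintf("x%02d", 3:12)),
               0.8)
  expect_equal(overlapCoefficient(sprintf("x%02d", 1:10),
                                  c(sprintf("x%02d", 1:5),
                                    sprintf("y%02d", 1:5))),
               0.5)
  expect_equal(overlapCoefficient(letters[1:3], letters[1:10]), 1)  # nested
  expect_error(overlapCoefficient(character(0), "a"), "empty")
})

test_that("merging collapses redundant sets and leaves disjoint ones alone", {
  shared <- sprintf("g%02d", 1:9)
  gsl <- GeneSetList(list(A = c(shared, "a10"), B = c(shared, "b10")))
  ss <- mergeGeneSets(gsl, rho = 0.33)
  expect_equal(nSets(ss), 1L)
  expect_length(geneSets(ss)[[1]], 11L)
  expect_setequal(memberSets(ss)[[1]], c("A", "B"))

  disj <- GeneSetList(list(A = letters[1:5], B = letters[6:10],
                           C = letters[11:15]))
  expect_equal(nSets(mergeGeneSets(disj)), 3L)

  nested <- GeneSetList(list(inner = letters[1:3], outer = letters[1:10]))
  expect_equal(nSets(mergeGeneSets(nested)), 1L)
})

test_that("merging conserves genes, is idempotent and respects rho", {
  set.seed(13)
  for (rep in 1:20) {
    gsl <- randomGeneSetList(sample(4:10, 1))
    rho <- 0.33
    ss <- mergeGeneSets(gsl, rho)
    expect_setequal(unique(unlist(geneSets(ss))),
                    unique(unlist(geneSets(gsl))))
    sets <- geneSets(ss)
    if (length(sets) >= 2) {
      for (i in seq_along(sets)) for (j in seq_len(i - 1))
        expect_lt(overlapCoefficient(sets[[i]], sets[[j]]), rho)
    }
    again <- mergeGeneSets(
      GeneSetList(setNames(ss@genes, ss@setId)), rho)
    expect_equal(unname(lapply(geneSets(again), sort)),
                 unname(lapply(geneSets(ss), sort)))
    expect_equal(nSets(again), nSets(ss))
  }
})

test_that("merge order is deterministic with a fixed tie rule", {
  gsl <- GeneSetList(list(B = c("x", "y", "z"), A = c("x", "y", "w"),
                          C = c("x", "q", "r")))
  s1 <- mergeGeneSets(gsl, rho = 0.5)
  s2 <- mergeGeneSets(gsl, rho = 0.5)
  expect_identical(geneSets(s1), geneSets(s2))
  expect_identical(memberSets(s1), memberSets(s2))
})

test_that("greedy agglomeration lands on a legal terminal partition (small n)", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(3:5, 1)
    sets <- lapply(seq_len(n), function(i) sample(letters[1:12],
                                                  sample(3:6, 1)))
    names(sets) <- sprintf("S%d", seq_len(n))
    rho <- 0.5
    ss <- mergeGeneSets(GeneSetList(sets), rho)
    got <- unname(lapply(memberSets(ss), sort))
    got <- got[order(vapply(got, paste, "", collapse = "|"))]
    legal <- allMergePartitions(sets, rho)
    keys <- vapply(legal, function(p)
      paste(vapply(p, paste, "", collapse = "|"), collapse = "||"), "")
    gotKey <- paste(vapply(got, paste, "", collapse = "|"), collapse = "||")
    expect_true(gotKey %in% keys)
  }
})

test_that("superset annotation keeps Bonferroni-significant terms only", {
  universe <- sprintf("u%03d", 1:100)
  s <- universe[1:10]
  terms <- GeneSetList(list(perfect = s,
                            half = c(universe[1:5], universe[51:55]),
                            off = universe[61:70]))
  ann <- annotateSuperset(s, terms, universe, alpha = 0.05)
  expect_equal(ann$term[1], "perfect")
  expect_false("off" %in% ann$term)
  # brute-force oracle for the half-overlap term
  pHalf <- bruteHyperTail(5, 10, 10, 100)
  i <- match("half", ann$term)
  if (!is.na(i)) expect_equal(ann$fisher_p[i], pHalf, tolerance = 1e-12)
  expect_equal(ann$bonferroni_p, pmin(1, ann$fisher_p * 3))

  # a term disjoint from the superset has one-sided p = 1 and is dropped
  p1 <- annotateSuperset(s, GeneSetList(list(off = universe[61:70])),
                         universe)
  expect_equal(nrow(p1), 0L)

  expect_error(annotateSuperset(c(s, "missing"), terms, universe),
               "universe")
})

test_that("second-round confirmation applies per-trait Bonferroni", {
  fx <- tinyIndex()
  one <- new("SupersetList", setId = "SS01", description = "",
             source = "test", genes = list(c("GA", "GB", "GC")),
             memberSets = list("A"), annotations = list(data.frame()))
  conf <- confirmSupersets(one, fx$index,
                           MseaParams(minGenes = 1L, nPerm = 400L, seed = 3L))
  # n = 1: Bonferroni reduces to the raw p
  expect_equal(conf$bonferroni_p, conf$pvalue)
  expect_equal(conf$pass, conf$pvalue < 0.05)
})

test_that("null supersets fail confirmation; planted ones pass", {
  cfg <- SimConfig(seed = 31L, nMarkers = 2000L, nGenes = 200L, nSets = 20L,
                   setSize = 15L, nSignalSets = 3L, signalPoolSize = 30L,
                   nPlantedKds = 0L)
  ms <- simulateMappingAndSets(cfg)
  gw <- simulateGwas(cfg, ms$truth$signalMarkers)
  idx <- buildGeneMarkerIndex(ms$map, gw$markers)
  params <- MseaParams(nPerm = 300L, seed = 1L, minGenes = 5L)

  # planted superset: union of the signal sets
  planted <- new("SupersetList", setId = "SSsig", description = "",
                 source = "signal", genes = list(ms$truth$signalGenes),
                 memberSets = list(ms$truth$signalSets),
                 annotations = list(data.frame()))
  confSig <- confirmSupersets(planted, idx, params)
  expect_true(confSig$pass)

  # 20 null supersets in null data: nearly all must fail
  cfg0 <- SimConfig(seed = 32L, nMarkers = 2000L, nGenes = 200L, nSets = 20L,
                    setSize = 15L, nSignalSets = 0L, nPlantedKds = 0L)
  ms0 <- simulateMappingAndSets(cfg0)
  gw0 <- simulateGwas(cfg0)
  idx0 <- buildGeneMarkerIndex(ms0$map, gw0$markers)
  nulls <- new("SupersetList", setId = sprintf("SS%02d", 1:20),
               description = rep("", 20), source = rep("null", 20),
               genes = ms0$sets@genes,
               memberSets = as.list(ms0$sets@setId),
               annotations = rep(list(data.frame()), 20))
  conf0 <- confirmSupersets(nulls, idx0, params)
  expect_lte(sum(conf0$pass, na.rm = TRUE), 1L)
})
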