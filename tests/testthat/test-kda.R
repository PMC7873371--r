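starNet <- function() DirectedGeneNetwork(data.frame(
  tail = c("H", "H", "H"), head = c("a", "b", "c"), n_studies = 2L))

test_that("neighborhoods follow depth and direction", {
  net <- starNet()
  expect_setequal(nodeNeighborhood(net, "H", 1, "out"), c("A", "B", "C"))
  expect_equal(nodeNeighborhood(net, "a", 1, "in"), "H")
  expect_equal(nodeNeighborhood(net, "a", 1, "out"), character(0))

  chain <- DirectedGeneNetwork(data.frame(tail = c("A", "B"),
                                          head = c("B", "C")))
  expect_setequal(nodeNeighborhood(chain, "A", 2, "out"), c("B", "C"))
  expect_equal(nodeNeighborhood(chain, "A", 1, "out"), "B")
  expect_setequal(nodeNeighborhood(chain, "B", 1, "both"), c("A", "C"))

  expect_error(nodeNeighborhood(net, "zz"), "not in the network")
  expect_error(KdaParams(depth = 4L), "1..3")
})

test_that("kda p-values equal the brute-force hypergeometric tail", {
  # 100 nodes, K = 20 superset genes, hub with 10 neighbors, 8 in S
  S <- sprintf("s%02d", 1:20)
  others <- sprintf("o%02d", 1:79)
  hub <- "HUB"
  tgt <- c(S[1:8], others[1:2])
  edges <- data.frame(tail = hub, head = tgt, n_studies = 1L)
  # ring over the remaining nodes so all 100 appear in the network
  rest <- setdiff(c(S, others), tgt)
  edges <- rbind(edges, data.frame(tail = rest,
                                   head = c(rest[-1], tgt[1]),
                                   n_studies = 1L))
  net <- DirectedGeneNetwork(edges)
  expect_length(networkNodes(net), 100L)
  res <- suppressMessages(kdaTest(net, S, KdaParams(minNbhd = 5L)))
  row <- res[res$gene == hub, ]
  expect_equal(row$n_nbhd, 10L)
  expect_equal(row$n_overlap, 8L)
  oracle <- sum(vapply(8:10, function(k)
    choose(20, k) * choose(79, 10 - k) / choose(99, 10), 0))
  expect_equal(row$pvalue, oracle, tolerance = 1e-12)
  expect_equal(row$fold_enrichment, (8 / 10) / (20 / 99))
})

test_that("the hub is excluded from population and successes", {
  # hub itself in S: K decremented
  S <- c("HUB", sprintf("s%02d", 1:19))
  others <- sprintf("o%02d", 1:80)
  tgt <- c(S[2:9], others[1:2])
  edges <- data.frame(tail = "HUB", head = tgt, n_studies = 1L)
  rest <- setdiff(c(S[-1], others), tgt)
  edges <- rbind(edges, data.frame(tail = rest, head = c(rest[-1], tgt[1]),
                                   n_studies = 1L))
  net <- DirectedGeneNetwork(edges)
  N <- length(networkNodes(net)) - 1
  res <- suppressMessages(kdaTest(net, S, KdaParams(minNbhd = 5L)))
  row <- res[res$gene == "HUB", ]
  oracle <- phyper(7, 19, N - 19, 10, lower.tail = FALSE)
  expect_equal(row$pvalue, oracle, tolerance = 1e-12)
})

test_that("hypergeometric tail equals full neighborhood enumeration (N <= 12)", {
  # population of N = 11 non-hub nodes, K = 4 in S, neighborhood size 5
  N <- 11; K <- 4; n <- 5; kObs <- 3
  oracle <- {
    combos <- combn(N, n)
    mean(apply(combos, 2, function(ix) sum(ix <= K) >= kObs))
  }
  expect_equal(phyper(kObs - 1, K, N - K, n, lower.tail = FALSE), oracle,
               tolerance = 1e-12)
  # and the same number through kdaTest on an explicit graph
  pop <- sprintf("n%02d", 1:11)
  S <- pop[1:4]
  tgt <- c(pop[1:3], pop[5:6])   # overlap 3 of 5
  edges <- rbind(data.frame(tail = "HUB", head = tgt, n_studies = 1L),
                 data.frame(tail = pop, head = c(pop[-1], "HUB"),
                            n_studies = 1L))
  res <- suppressMessages(kdaTest(DirectedGeneNetwork(edges), S,
                                  KdaParams(minNbhd = 5L)))
  expect_equal(res$pvalue[res$gene == "HUB"], oracle, tolerance = 1e-12)
})

test_that("node-label permutation agrees with the hypergeometric p", {
  set.seed(44)
  cfg <- SimConfig(seed = 77L, netNodes = 300L, outDegreeMean = 15,
                   nPlantedKds = 0L, nSignalSets = 0L)
  nw <- simulateNetwork(cfg)
  nodes <- nw$nodes
  S <- sample(nodes, 60)
  res <- suppressMessages(kdaTest(nw$network, S, KdaParams()))
  hubs <- sample(res$gene, 20)
  g <- igraph::graph_from_data_frame(
    networkEdges(nw$network)[, c("tail", "head")], directed = TRUE)
  for (h in hubs) {
    nb <- names(igraph::ego(g, 1, nodes = h, mode = "out", mindist = 1)[[1]])
    obs <- sum(nb %in% S)
    pool <- setdiff(nodes, h)
    K <- length(intersect(S, pool))
    nPerm <- 1000
    cnt <- vapply(seq_len(nPerm), function(i)
      sum(nb %in% sample(pool, K)) >= obs, TRUE)
    pPerm <- (1 + sum(cnt)) / (nPerm + 1)
    pHyper <- res$pvalue[res$gene == h]
    se <- sqrt(pHyper * (1 - pHyper) / nPerm)
    expect_lt(abs(pPerm - pHyper), 4 * se + 2 / nPerm)
  }
})

test_that("kda output is deterministic and handles degenerate supersets", {
  net <- starNet()
  r1 <- suppressMessages(kdaTest(net, c("A", "B"), KdaParams(minNbhd = 2L)))
  r2 <- suppressMessages(kdaTest(net, c("A", "B"), KdaParams(minNbhd = 2L)))
  expect_identical(r1, r2)

  # superset disjoint from a hub's neighborhood: not a key driver
  S <- c("X", "Y")
  net2 <- DirectedGeneNetwork(data.frame(
    tail = c("H", "H", "H", "X"), head = c("a", "b", "c", "Y")))
  res <- suppressMessages(kdaTest(net2, S, KdaParams(minNbhd = 3L)))
  row <- res[res$gene == "H", ]
  expect_equal(row$n_overlap, 0L)
  expect_gte(row$pvalue, 0.5)
  expect_false(row$is_kd)

  # superset absent from the network: empty result, no exception
  out <- suppressMessages(kdaTest(net, c("QQ1", "QQ2")))
  expect_equal(nrow(out), 0L)
})

test_that("subnetwork export keeps KD-incident superset edges only", {
  edges <- data.frame(tail = "KD1",
                      head = c("s1", "s2", "s3", "x1", "x2"),
                      n_studies = 2L)
  net <- DirectedGeneNetwork(edges)
  sub <- exportSubnetwork(net, "KD1", c("s1", "s2", "s3"),
                          KdaParams(edgeMinStudies = 2L))
  expect_equal(nrow(sub), 3L)
  expect_setequal(sub$head, c("S1", "S2", "S3"))
  expect_true(all(sub$tail_is_kd))
  expect_false(any(sub$head_is_kd))

  expect_error(exportSubnetwork(net, character(0), "s1"), "non-empty")

  weak <- DirectedGeneNetwork(data.frame(tail = "KD1", head = "s1",
                                         n_studies = 1L))
  expect_warning(empty <- exportSubnetwork(weak, "KD1", "s1",
                                           KdaParams(edgeMinStudies = 2L)),
                 "no edges")
  expect_equal(nrow(empty), 0L)
})

test_that("exported edges carry the head gene's best GWAS p", {
  net <- DirectedGeneNetwork(data.frame(tail = "KD1", head = c("s1", "s2"),
                                        n_studies = 2L))
  map <- MarkerGeneMap(data.frame(marker_id = c("m1", "m2", "m3"),
                                  gene_id = c("s1", "s1", "s2"),
                                  source = "x"))
  markers <- data.frame(marker_id = c("m1", "m2", "m3"),
                        pvalue = c(0.2, 1e-6, 0.5))
  sub <- exportSubnetwork(net, "KD1", c("s1", "s2"),
                          KdaParams(edgeMinStudies = 1L), map, markers)
  expect_equal(sub$head_best_gwas_p[sub$head == "S1"], 1e-6)
  expect_equal(sub$head_best_gwas_p[sub$head == "S2"], 0.5)
})
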