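stringToyFile <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score", rows), path)
  path
}

test_that("STRING ingestion thresholds, canonicalizes and errors usefully", {
  p <- stringToyFile(c("A\tB\t950", "B\tC\t920", "C\tD\t300"))
  net <- loadStringEdges(p, minScore = 900)
  expect_equal(igraph::ecount(asIgraph(net)), 2)
  expect_setequal(networkGenes(net), c("A", "B", "C"))

  # boundary: 899 excluded, 900 included
  p2 <- stringToyFile(c("A\tB\t899", "B\tC\t900"))
  net2 <- loadStringEdges(p2)
  expect_equal(igraph::ecount(asIgraph(net2)), 1)
  expect_setequal(networkGenes(net2), c("B", "C"))

  # duplicate pair collapsed keeping max score
  p3 <- stringToyFile(c("A\tB\t950", "B\tA\t910"))
  net3 <- loadStringEdges(p3)
  expect_equal(igraph::ecount(asIgraph(net3)), 1)
  expect_equal(igraph::E(asIgraph(net3))$score, 950)

  expect_error(loadStringEdges(stringToyFile("A\tB\t500")), "threshold")
  expect_error(loadStringEdges(tempfile()), "not found")
})

test_that("identifier mapping is applied before thresholding", {
  p <- stringToyFile(c("9606.P1\t9606.P2\t950"))
  net <- loadStringEdges(p, idMap = data.frame(
    from = c("9606.P1", "9606.P2"), to = c("GENEA", "GENEB")))
  expect_setequal(networkGenes(net), c("GENEA", "GENEB"))
})

test_that("harmonic distance matches hand computation and clique bound", {
  p <- stringToyFile(c("A\tB\t950", "B\tC\t950"))
  net <- loadStringEdges(p)
  # pairwise d = (1, 1, 2): H = 3 / (1 + 1 + 0.5)
  expect_equal(harmonicDistance(net, c("A", "B", "C")), 1.2)
  # clique: all pairwise d = 1 -> H = 1
  p2 <- stringToyFile(c("A\tB\t950", "B\tC\t950", "A\tC\t950"))
  expect_equal(harmonicDistance(loadStringEdges(p2), c("A", "B", "C")), 1)
  expect_error(harmonicDistance(net, c("A", "ZZZ")), "ZZZ")
})

test_that("harmonic distance equals the BFS oracle on random graphs", {
  for (i in 1:25) {
    n <- sample(6:30, 1)
    adj <- randomGraph(n, runif(1, 0.1, 0.35), seed = 5000 + i)
    if (sum(adj) == 0) next
    net <- graphFromAdj(adj)
    nodes <- networkGenes(net)
    seedIdx <- sort(sample(n, sample(3:min(8, n), 1)))
    em <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
    expect_equal(harmonicDistance(net, nodes[seedIdx]),
                 harmonicOracle(em, n, seedIdx),
                 info = paste("graph", i))
  }
})

test_that("colocalization permutation p behaves and planted cliques score low", {
  set.seed(21)
  cfg <- simulationConfig(nGenes = 150L,
                          network = list(moduleSize = 6L))
  net <- simulateNetwork(cfg, seed = 13)
  res <- colocalizationTest(net$network, net$truth$moduleGenes,
                            nPerm = 200, seed = 5)
  expect_equal(res@dObs, 1)               # planted clique
  expect_lte(res@p, 0.01 + 1 / 201)
  expect_length(res@dNull, 200)
  expect_gt(mean(res@dNull), res@dObs)
})

test_that("colocalization p is uniform under a random-seed null", {
  cfg <- simulationConfig(nGenes = 120L)
  net <- simulateNetwork(cfg, plantModule = FALSE, seed = 2)
  nodes <- networkGenes(net$network)
  ps <- vapply(1:200, function(i) {
    seeds <- withr::with_seed(3000 + i, sample(nodes, 8))
    colocalizationTest(net$network, seeds, nPerm = 49,
                       seed = 7000 + i)@p
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("MCODE weights and complexes match hand-run toys", {
  # 4-clique (n1..n4) plus pendant n5 attached to n1
  adj <- matrix(0L, 5, 5)
  for (i in 1:4) for (j in 1:4) if (i != j) adj[i, j] <- 1L
  adj[1, 5] <- adj[5, 1] <- 1L
  net <- graphFromAdj(adj)
  w <- MethylModule:::mcodeVertexWeights(asIgraph(net))
  # vertices 2-4: open neighbourhood is a 3-clique (+ n5 for none):
  # core number 2, density 1 -> weight 2
  expect_equal(w[2:4], rep(2, 3))
  res <- runMcode(net, seeds = "n01")
  expect_setequal(res@genes, c("n01", "n02", "n03", "n04"))

  # no-edges-above-cutoff degenerate case: empty module, no error
  adj0 <- matrix(0L, 4, 4); adj0[1, 2] <- adj0[2, 1] <- 1L
  res0 <- runMcode(graphFromAdj(adj0), seeds = "n03")
  expect_length(res0@genes, 0)
})

test_that("MCODE vertex weight in a k-clique is (k-2) * 1", {
  for (k in 4:6) {
    adj <- matrix(1L, k, k); diag(adj) <- 0L
    w <- MethylModule:::mcodeVertexWeights(asIgraph(graphFromAdj(adj)))
    expect_equal(w, rep(k - 2, k))
  }
})

test_that("DIAMOnD picks the best-connected candidate on the toy", {
  # s1-a, s2-a, s1-b; seeds {s1, s2}: a (k=2, ks=2) beats b (k=1, ks=1)
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("s1", "s2", "s1"), to = c("a", "a", "b"),
               score = 950), directed = FALSE)
  net <- methods::new("PPINetwork", graph = g, minScore = 900)
  res <- runDiamond(net, c("s1", "s2"), nAdded = 1)
  expect_setequal(res@genes, c("s1", "s2", "a"))
  expect_equal(res@parameters$added, "a")
  expect_error(runDiamond(net, c("s1", "s2"), nAdded = 0), "nAdded")
  expect_error(runDiamond(net, "zz"), "seed")
})

test_that("DIAMOnD ranking equals the exhaustive hypergeometric oracle", {
  for (i in 1:12) {
    n <- sample(10:25, 1)
    adj <- randomGraph(n, 0.25, seed = 800 + i)
    if (sum(adj) < 4) next
    net <- graphFromAdj(adj)
    nodes <- networkGenes(net)
    seeds <- sample(nodes, 3)
    res <- runDiamond(net, seeds, nAdded = 6)
    oracle <- diamondOracle(adj, nodes, seeds, 6)
    expect_equal(res@parameters$added, oracle, info = paste("graph", i))
  }
})

test_that("clique enumeration matches the brute-force oracle", {
  for (i in 1:20) {
    n <- sample(8:16, 1)
    adj <- randomGraph(n, 0.35, seed = 900 + i)
    ours <- igraph::max_cliques(asIgraph(graphFromAdj(adj)), min = 3)
    ours <- lapply(ours, function(cl) sort(as.integer(cl)))
    oracle <- maximalCliqueOracle(adj, minSize = 3)
    expect_setequal(lapply(ours, paste, collapse = "-"),
                    lapply(oracle, paste, collapse = "-"))
  }
})

test_that("Clique Sum keeps seed-enriched cliques and only those", {
  # 4-clique of seeds inside a sparse 100-node background
  set.seed(10)
  adj <- randomGraph(100, 0.01, seed = 44)
  for (i in 1:4) for (j in 1:4) if (i != j) adj[i, j] <- 1L
  net <- graphFromAdj(adj)
  seeds <- sprintf("n%02d", 1:4)
  res <- runCliqueSum(net, seeds)
  expect_setequal(res@genes, seeds)
  # no seeds in any clique -> empty module
  res0 <- runCliqueSum(net, "n99")
  expect_length(res0@genes, 0)
})

test_that("Correlation Clique honors its deterministic limits", {
  # all-seed triangle with perfect scores inside a clique-free
  # background: retention probability 1, so the module equals the
  # triangle for any iteration count
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B", "C", "D", "E", "F", "G", "H", "I"),
               to = c("B", "C", "A", "E", "F", "A", "H", "I", "J"),
               score = 1000), directed = FALSE)
  net <- methods::new("PPINetwork", graph = g, minScore = 900)
  res <- runCorrelationClique(net, c("A", "B", "C"),
                              seedScores = c(A = 1, B = 1, C = 1),
                              nIter = 5, rngSeed = 1)
  expect_setequal(res@genes, c("A", "B", "C"))
  # zero retention probability: empty module
  net0 <- methods::new("PPINetwork", graph = igraph::set_edge_attr(
    g, "score", value = 0), minScore = 0)
  res0 <- runCorrelationClique(net0, c("A", "B", "C"), nIter = 5,
                               rngSeed = 1)
  expect_length(res0@genes, 0)
  expect_error(runCorrelationClique(net, "A", nIter = 1), "nIter")
})

test_that("Correlation Clique recovers a planted high-score seed clique", {
  hits <- vapply(1:20, function(r) {
    adj <- randomGraph(40, 0.08, seed = 600 + r)
    for (i in 1:5) for (j in 1:5) if (i != j) adj[i, j] <- 1L
    nodes <- sprintf("n%02d", 1:40)
    idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
    score <- ifelse(idx[, 1] <= 5 & idx[, 2] <= 5, 990, 910)
    g <- igraph::graph_from_data_frame(
      data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                 score = score), directed = FALSE, vertices = nodes)
    net <- methods::new("PPINetwork", graph = g, minScore = 900)
    res <- runCorrelationClique(net, nodes[1:5], nIter = 50,
                                rngSeed = 7 + r)
    all(nodes[1:5] %in% res@genes)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("the consensus rule is exactly membership in >= 3 of 4", {
  mk <- function(method, genes) methods::new("ModuleResult",
    method = method, genes = genes,
    scores = setNames(rep(1, length(genes)), genes),
    seeds = "g1", parameters = list())
  methodsAll <- c("mcode", "diamond", "clique_sum", "correlation_clique")
  # exhaustive: all 16 membership patterns over one gene
  for (code in 0:15) {
    inMethod <- as.logical(bitwAnd(code, 2^(0:3)))
    results <- lapply(1:4, function(i)
      mk(methodsAll[i], if (inMethod[i]) c("g1", "gX") else "gX"))
    cons <- buildConsensus(results, minMethods = 3)
    expect_equal("g1" %in% cons@genes, sum(inMethod) >= 3,
                 info = paste("pattern", code))
  }
  expect_error(buildConsensus(list(mk("mcode", "a"), mk("mcode", "b"),
                                   mk("diamond", "c"),
                                   mk("clique_sum", "d"))),
               "duplicate")
  expect_error(buildConsensus(list(mk("mcode", "a"))), "exactly 4")
})

test_that("module CpG projection carries contrast effects and bookkeeping", {
  cfg <- fastConfig(seed = 12)
  sim <- simulateCohort(cfg)
  ann <- probeGenes(sim$dataset)
  dmps <- data.frame(probe = ann$probe, contrast = "T2_vs_NP",
                     deltaBeta = 0.1, q = 0.01, isDMP = TRUE)
  gene1 <- ann$gene[1]
  out <- moduleToCpgs(gene1, ann, dmps)
  expect_setequal(out$probe, ann$probe[ann$gene == gene1])
  expect_warning(moduleToCpgs(c(gene1, "NOSUCHGENE"), ann, dmps),
                 "NOSUCHGENE")
  # synthetic bookkeeping: module CpGs equal the truth map restriction
  genes <- unique(ann$gene)[1:5]
  out5 <- suppressWarnings(moduleToCpgs(genes, ann, dmps))
  truthSet <- sim$truth$probeGeneMap
  expect_setequal(out5$probe,
                  unique(truthSet$probe[truthSet$gene %in% genes]))
})
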