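test_that("latent profiles honor clipping, k=1 identity and planted diffs", {
  p1 <- simulateProfiles(500, 1, seed = 4)
  expect_equal(ncol(p1$mu), 1)
  expect_length(p1$diffProbes, 0)
  for (s in c(1, 9, 33)) {
    pr <- simulateProfiles(1000, 2, seed = s, diffFraction = 0.3)
    expect_true(all(pr$mu >= 0.01 & pr$mu <= 0.99))
    nBig <- sum(abs(pr$mu[, 1] - pr$mu[, 2]) >= 0.2)
    expect_equal(nBig, length(pr$diffProbes))
    expect_equal(nBig, floor(0.3 * 1000))
  }
  expect_error(simulateProfiles(5, 2), "nProbes")
  expect_error(simulateProfiles(100, 0), "kTrue")
})

test_that("cohort betas sit on the mixture mean in the noiseless limit", {
  cfg <- fastConfig(seed = 2, noisePrecision = Inf, nEffect = 0L,
                    qcArtifactRates = c(detP = 0, bead = 0, noCpG = 0,
                                        snp = 0, multi = 0))
  sim <- simulateCohort(cfg)
  b <- betaValues(sim$dataset)
  mu <- sim$truth$mu
  om <- sim$truth$omega[colnames(b), ]
  expect_equal(unname(b), unname(mu %*% t(om)), tolerance = 1e-3)
  expect_true(all(abs(rowSums(sim$truth$omega) - 1) < 1e-9))
})

test_that("planted delta-beta is realised empirically", {
  # Monte-Carlo mean over replicates at the study's group sizes
  diffs <- vapply(1:50, function(r) {
    cfg <- simulationConfig(nProbes = 60L, nGenes = 20L, nEffect = 5L,
                            deltaBeta = 0.10, seed = 1000 + r,
                            qcArtifactRates = c(detP = 0, bead = 0,
                                                noCpG = 0, snp = 0,
                                                multi = 0))
    sim <- simulateCohort(cfg)
    eff <- sim$truth$effects[1, ]
    g <- sim$truth$groups
    b <- betaValues(sim$dataset)[eff$probe, ]
    (mean(b[g == "T2"]) - mean(b[g == "NP"])) * sign(eff$deltaBeta)
  }, 0)
  expect_lt(abs(mean(diffs) - 0.10), 0.03)

  # convergence of the empirical difference at n = 200 per group
  cfgBig <- simulationConfig(
    nProbes = 300L, nGenes = 60L, nEffect = 30L, seed = 11,
    groups = data.frame(label = c("NP", "T1", "T2"),
                        n = c(200L, 3L, 200L)),
    qcArtifactRates = c(detP = 0, bead = 0, noCpG = 0, snp = 0,
                        multi = 0))
  simB <- simulateCohort(cfgBig)
  g <- simB$truth$groups
  b <- betaValues(simB$dataset)
  eff <- simB$truth$effects
  emp <- rowMeans(b[eff$probe, g == "T2"]) -
    rowMeans(b[eff$probe, g == "NP"])
  expect_lt(max(abs(emp - eff$deltaBeta)), 0.01 + 0.01)
  expect_lt(abs(mean(emp - eff$deltaBeta)), 0.01)
})

test_that("emitted betas stay inside (0,1) and ground truth ids exist", {
  cfg <- fastConfig(seed = 5)
  sim <- simulateCohort(cfg)
  b <- betaValues(sim$dataset)
  expect_true(all(b > 0 & b < 1))
  expect_true(all(sim$truth$effects$probe %in% rownames(b)))
  expect_true(all(unlist(sim$truth$qc) %in% rownames(b)))
  expect_true(all(sim$truth$probeGeneMap$probe %in% rownames(b)))
})

test_that("preferential-attachment background has the closed-form edge count", {
  cfg <- simulationConfig(nGenes = 200L, network = list(m = 2L))
  net <- simulateNetwork(cfg, plantModule = FALSE, seed = 3)
  g <- asIgraph(net$network)
  expect_equal(igraph::ecount(g), 2 * (200 - 2) + 1)
  expect_true(igraph::is_connected(g))
  expect_true(all(igraph::E(g)$score >= 900))
})

test_that("the planted module is a clique drawn from the effect genes", {
  cfg <- fastConfig(seed = 6, network = list(moduleSize = 5L))
  sim <- simulateCohort(cfg)
  effGenes <- unique(sim$truth$effects$gene)
  net <- simulateNetwork(cfg, effectGenes = effGenes, seed = 6)
  mod <- net$truth$moduleGenes
  expect_length(mod, 5)
  sub <- igraph::induced_subgraph(asIgraph(net$network), mod)
  expect_equal(igraph::ecount(sub), choose(5, 2))
  expect_error(simulateNetwork(fastConfig(network = list(moduleSize = 2L))),
               "module size")
})

test_that("disease cohorts respect sign, overlap floor and correlation", {
  cfg <- fastConfig(seed = 8,
                    disease = list(nControls = 10L,
                                   overlapFraction = 0.3,
                                   effectSign = -1))
  sim <- simulateCohort(cfg)
  dz <- simulateDiseaseCohort(cfg, sim$truth, seed = 8)
  eff <- dz$truth$effects
  expect_true(all(sign(eff$deltaBeta) ==
                  -sign(eff$pregnancyDeltaBeta)))
  expect_length(dz$truth$overlapControls, 3)   # floor(0.3 * 10)
  expect_true(all(dz$truth$overlapControls %in%
                  colnames(betaValues(dz$dataset))))

  cfgPos <- fastConfig(seed = 8, disease = list(effectSign = 1))
  simP <- simulateCohort(cfgPos)
  dzP <- simulateDiseaseCohort(cfgPos, simP$truth, seed = 9)
  effP <- dzP$truth$effects
  expect_gte(nrow(effP), 20)
  expect_equal(cor(effP$deltaBeta, effP$pregnancyDeltaBeta), 1)

  badCfg <- fastConfig()
  badCfg$disease$overlapFraction <- 1
  expect_error(simulateDiseaseCohort(badCfg, sim$truth), "overlap")
  badCfg2 <- fastConfig()
  badCfg2$disease$effectSign <- 2
  expect_error(simulateDiseaseCohort(badCfg2, sim$truth), "sign")
})

test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(deltaBeta = 0.6), "0, 0.5")
  expect_error(simulationConfig(meanProps = rbind(c(0.6, 0.5),
                                                  c(0.5, 0.5),
                                                  c(0.5, 0.5))),
               "sum to 1")
  expect_error(simulationConfig(kTrue = 3), "kTrue")
  expect_error(simulationConfig(nProbes = 0), "positive")
})
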