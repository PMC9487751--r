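test_that("design matrix has full rank and names collinear columns", {
  g <- rep(c("NP", "T1", "T2"), c(4, 4, 4))
  om <- cbind(runif(12, 0.2, 0.8)); om <- cbind(om, 1 - om)
  X <- buildDesign(g, om)
  expect_equal(qr(X)$rank, ncol(X))
  expect_equal(ncol(X), 4)            # intercept, T1, T2, omega2
  # full omega block with an intercept is collinear
  Xbad <- cbind(model.matrix(~factor(g)), om)
  expect_error(buildDesign(g, cbind(om, rowSums(om))), "collinear")
})

test_that("single-probe toy recovers the closed-form OLS contrast", {
  M <- rbind(c(1, 1, 1, 3, 3, 3),
             c(1, 1, 1, 3, 3, 3) + rnorm(6, 0, 1e-12))
  dimnames(M) <- list(c("cg1", "cg2"), sprintf("s%d", 1:6))
  g <- rep(c("A", "B"), each = 3)
  design <- buildDesign(g)
  st <- fitProbeModels(M, design, groups = g, moderated = FALSE)
  row <- st[st$probe == "cg1" & st$contrast == "B_vs_A", ]
  expect_equal(row$coef, 2, tolerance = 1e-9)
  expect_lt(row$p, 1e-6)
})

test_that("moderation is a no-op when residual variances are equal", {
  set.seed(8)
  e <- c(-1, 1, 0.5, -0.5, 0, 0)       # same residuals for every probe
  M <- t(sapply(1:30, function(i) i / 10 + e))
  rownames(M) <- sprintf("cg%02d", 1:30)
  colnames(M) <- sprintf("s%d", 1:6)
  g <- rep(c("A", "B"), 3)
  design <- buildDesign(g)
  mod <- fitProbeModels(M, design, groups = g, moderated = TRUE)
  ols <- fitProbeModels(M, design, groups = g, moderated = FALSE)
  expect_equal(mod$t, ols$t, tolerance = 1e-6)
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(adjustFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustFdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjustFdr(0.013), 0.013)
  p <- runif(50)
  expect_true(all(diff(adjustFdr(sort(p))) >= 0))
})

test_that("delta-beta is the difference of group means", {
  b <- rbind(cg1 = c(0.5, 0.6, 0.4, 0.5), cg2 = c(0.4, 0.4, 0.5, 0.5))
  g <- c("NP", "NP", "T2", "T2")
  db <- computeDeltaBeta(b, g, c("NP", "T2"))
  expect_equal(unname(db), c(-0.10, 0.10))
  expect_equal(unname(computeDeltaBeta(b, g, c("NP", "NP"))), c(0, 0))
  expect_error(computeDeltaBeta(b, g, c("NP", "T9")), "empty")
})

test_that("planted delta-beta is recovered within 0.01 at n = 200/group", {
  cfg <- simulationConfig(
    nProbes = 200L, nGenes = 50L, nEffect = 20L, seed = 31,
    groups = data.frame(label = c("NP", "T1", "T2"),
                        n = c(200L, 3L, 200L)))
  sim <- simulateCohort(cfg)
  db <- computeDeltaBeta(betaValues(sim$dataset), sim$truth$groups,
                         c("NP", "T2"))
  eff <- sim$truth$effects
  expect_lt(mean(abs(db[eff$probe] - eff$deltaBeta)), 0.01)
})

test_that("DMP calling applies both strict thresholds and is monotone", {
  st <- data.frame(probe = c("a", "b", "c"), contrast = "T2_vs_NP",
                   coef = 1, t = 1,
                   p = c(0.0006, 0.0024, 0.0004), df = 10)
  db <- c(a = 0.04, b = 0.20, c = -0.08)
  out <- callDmps(st, db, qThresh = 0.05, dbThresh = 0.05)
  expect_equal(out$q >= out$p, rep(TRUE, 3))
  # a: q ok but |db| = 0.04 fails the 5% rule
  expect_false(out$isDMP[out$probe == "a"])
  expect_equal(out$direction[out$probe == "c"], "hypo")
  expect_true(out$isDMP[out$probe == "c"])
  # q above threshold fails however large the delta
  st2 <- st; st2$p <- c(0.9, 0.9, 0.9)
  out2 <- callDmps(st2, db)
  expect_false(any(out2$isDMP))
  # monotone: tightening thresholds never adds calls
  for (i in 1:10) {
    p <- runif(20); dbv <- setNames(runif(20, -0.3, 0.3), letters[1:20])
    stR <- data.frame(probe = letters[1:20], contrast = "c1",
                      coef = 1, t = 1, p = p, df = 10)
    loose <- callDmps(stR, dbv, 0.2, 0.02)$isDMP
    tight <- callDmps(stR, dbv, 0.05, 0.08)$isDMP
    expect_true(all(loose[tight]))
  }
  expect_error(callDmps(st, c(zz = 1)), "misaligned|named")
})

test_that("DMG mapping follows the majority rule with the stated tie-break", {
  dmps <- data.frame(
    probe = c("p1", "p2", "p3", "p4", "p5"),
    contrast = "T2_vs_NP",
    q = c(0.001, 0.02, 0.04, 0.001, 0.04),
    deltaBeta = c(0.1, 0.1, -0.1, 0.2, -0.2),
    direction = c("hyper", "hyper", "hypo", "hyper", "hypo"),
    isDMP = TRUE)
  ann <- data.frame(probe = c("p1", "p2", "p3", "p4", "p5"),
                    gene = c("G1", "G1", "G1", "G2", "G2"))
  dmg <- mapDmpsToGenes(dmps, ann)
  expect_equal(dmg$direction[dmg$gene == "G1"], "hyper")  # 2 vs 1
  # G2 ties 1-1: smallest-q member is hyper
  expect_equal(dmg$direction[dmg$gene == "G2"], "hyper")
  # single hypo DMP
  dmg3 <- mapDmpsToGenes(dmps[3, ], ann)
  expect_equal(dmg3$direction, "hypo")
  # multi-gene probes count for each mapped gene
  ann2 <- rbind(ann, data.frame(probe = "p1", gene = "G9"))
  dmg2 <- mapDmpsToGenes(dmps, ann2)
  expect_true("G9" %in% dmg2$gene)
})

test_that("null cohorts produce calibrated p-values and ~no DMPs", {
  cfg <- simulationConfig(nProbes = 2000L, nGenes = 300L, nEffect = 0L,
                          groups = data.frame(label = c("NP", "T2"),
                                              n = c(12L, 12L)),
                          meanProps = rbind(NP = c(0.55, 0.45),
                                            T2 = c(0.55, 0.45)),
                          seed = 17,
                          qcArtifactRates = c(detP = 0, bead = 0,
                                              noCpG = 0, snp = 0,
                                              multi = 0))
  sim <- simulateCohort(cfg)
  dmps <- dmpTable(sim$dataset, sim$truth$omega)
  p <- dmps$p[dmps$contrast == "T2_vs_NP"]
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
  expect_lte(sum(dmps$isDMP), 2)
})

test_that("omega adjustment removes composition-driven differences", {
  # groups differ ONLY through mixing proportions
  cfg <- simulationConfig(nProbes = 1200L, nGenes = 200L, nEffect = 0L,
                          meanProps = rbind(NP = c(0.75, 0.25),
                                            T1 = c(0.60, 0.40),
                                            T2 = c(0.30, 0.70)),
                          seed = 23,
                          qcArtifactRates = c(detP = 0, bead = 0,
                                              noCpG = 0, snp = 0,
                                              multi = 0))
  sim <- simulateCohort(cfg)
  adj <- dmpTable(sim$dataset, sim$truth$omega)
  unadj <- dmpTable(sim$dataset, NULL)
  nAdj <- sum(adj$isDMP & adj$contrast == "T2_vs_NP")
  nUnadj <- sum(unadj$isDMP & unadj$contrast == "T2_vs_NP")
  expect_lte(nAdj, 5)
  expect_gt(nUnadj, 50)
})

test_that("planted effects are recovered with high sensitivity", {
  cfg <- simulationConfig(seed = 9, deltaBeta = 0.10)
  sim <- simulateCohort(cfg)
  f <- filterProbes(sim$dataset)
  dec <- refFreeDecompose(f, 2, seed = 9)
  dmps <- dmpTable(f, cellProportions(dec))
  called <- dmps$probe[dmps$isDMP & dmps$contrast == "T2_vs_NP"]
  sens <- mean(sim$truth$effects$probe %in% called)
  expect_gte(sens, 0.8)
  # empirical FDR among calls controlled near the nominal level
  fdr <- mean(!(called %in% sim$truth$effects$probe))
  expect_lte(fdr, 0.05 + 2 * sqrt(0.05 * 0.95 / length(called)))
})

test_that("classical MDS recovers exact low-rank configurations", {
  set.seed(33)
  pts <- cbind(rnorm(8), rnorm(8))
  # build a beta-like matrix whose sample distances equal those of pts
  B <- rbind(t(pts) / 10 + 0.5, matrix(0.5, 3, 8))
  rownames(B) <- sprintf("cg%d", 1:5); colnames(B) <- sprintf("s%d", 1:8)
  mds <- mdsCoordinates(B, nTop = 5, nComponents = 2)
  d0 <- dist(pts / 10)
  expect_equal(as.matrix(dist(mds$coords)), as.matrix(d0),
               tolerance = 1e-8, ignore_attr = TRUE)
  # duplicated samples coincide
  B2 <- B; B2[, 2] <- B2[, 1]
  mds2 <- mdsCoordinates(B2, nTop = 5, nComponents = 2)
  expect_equal(mds2$coords[1, ], mds2$coords[2, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  # variance explained is non-increasing and sums to at most 1
  cfg <- fastConfig(seed = 3)
  sim <- simulateCohort(cfg)
  mv <- mdsCoordinates(sim$dataset, nTop = 300, nComponents = 6)
  expect_true(all(diff(mv$varExplained) <= 1e-12))
  expect_lte(sum(mv$varExplained), 1 + 1e-12)
  w <- capture_warnings(mdsCoordinates(B, nComponents = 20))
  expect_true(any(grepl("truncated", w)))
  expect_error(mdsCoordinates(B[, 1:2]), "3 samples")
})
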