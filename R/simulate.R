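#' Simulation configuration for synthetic methylation cohorts
#'
#' Bundles every generative assumption behind the synthetic cohorts: a
#' three-group design (non-pregnant NP n=12, first trimester T1 n=11,
#' second trimester T2 n=12, mirroring the motivating study design), two
#' latent cell types (naive/memory analogue) whose mixing proportions
#' shift across groups, beta-distributed observation noise around the
#' mixture mean, planted group effects of a few percent delta-beta,
#' probe-level QC artifacts, a scale-free interaction network with a
#' planted dense module among the effect genes, and disease cohorts with
#' a configurable effect sign relative to the pregnancy effects and a
#' partially overlapping (case-like) control subgroup.
#'
#' @param nProbes,nGenes probe and gene universe sizes.
#' @param groups data.frame with columns \code{label} and \code{n}.
#' @param meanProps groups x kTrue matrix of mean mixing proportions
#'   (rows sum to 1).
#' @param kTrue number of latent cell types.
#' @param omegaConcentration Dirichlet precision of per-sample mixing
#'   proportions around the group mean.
#' @param nEffect number of planted effect probes (T2 vs NP contrast).
#' @param deltaBeta planted effect magnitude on the beta scale, in
#'   (0, 0.5): a scalar for a constant magnitude, or a length-2 range
#'   sampled uniformly per probe (default 0.05-0.15).
#' @param hyperFraction fraction of effect probes with positive sign.
#' @param effectCellType \code{"all"} (effect shifts the full mixture
#'   mean) or a cell-type index whose latent profile carries the effect.
#' @param noisePrecision beta-distribution concentration of observation
#'   noise (\code{Inf} = noiseless).
#' @param profileDiffFraction,profileMinDiff fraction of probes whose
#'   latent profiles differ between cell types, and the minimum
#'   difference.
#' @param qcArtifactRates named fractions for the five QC filters
#'   (\code{detP}, \code{bead}, \code{noCpG}, \code{snp}, \code{multi}).
#' @param network list: \code{nNodes} (default \code{nGenes}), attachment
#'   parameter \code{m}, \code{moduleSize}, \code{plantClique},
#'   \code{minScore}, \code{coLocalizeEffects} (extra effect-gene edges
#'   per effect gene).
#' @param disease list: \code{nCases}, \code{nControls},
#'   \code{overlapFraction} in [0,1), \code{effectSign} in \{-1, +1\},
#'   \code{sharedFraction} of pregnancy effect probes reused,
#'   \code{deltaBeta} (NULL = inherit each probe's pregnancy
#'   magnitude), \code{meanProps} (mixing proportions shared by cases
#'   and controls).
#' @param seed master integer seed; all randomness is derived from it.
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nProbes = 2000L, nGenes = 400L,
    groups = data.frame(label = c("NP", "T1", "T2"), n = c(12L, 11L, 12L)),
    meanProps = rbind(NP = c(0.65, 0.35), T1 = c(0.60, 0.40),
                      T2 = c(0.45, 0.55)),
    kTrue = 2L, omegaConcentration = 8,
    nEffect = 100L, deltaBeta = c(0.05, 0.15), hyperFraction = 2 / 3,
    effectCellType = "all", noisePrecision = 200,
    profileDiffFraction = 0.3, profileMinDiff = 0.2,
    qcArtifactRates = c(detP = 0.01, bead = 0.005, noCpG = 0.002,
                        snp = 0.02, multi = 0.001),
    network = list(), disease = list(), seed = 1L) {
  network <- utils::modifyList(list(nNodes = nGenes, m = 2L,
      moduleSize = 8L, plantClique = TRUE, minScore = 900L,
      coLocalizeEffects = 0.5), network)
  disease <- utils::modifyList(list(nCases = 20L, nControls = 20L,
      overlapFraction = 0.3, effectSign = -1, sharedFraction = 0.6,
      deltaBeta = NULL, meanProps = c(0.55, 0.45)), disease)
  cfg <- list(nProbes = as.integer(nProbes), nGenes = as.integer(nGenes),
              groups = groups, meanProps = as.matrix(meanProps),
              kTrue = as.integer(kTrue),
              omegaConcentration = omegaConcentration,
              nEffect = as.integer(nEffect), deltaBeta = deltaBeta,
              hyperFraction = hyperFraction,
              effectCellType = effectCellType,
              noisePrecision = noisePrecision,
              profileDiffFraction = profileDiffFraction,
              profileMinDiff = profileMinDiff,
              qcArtifactRates = qcArtifactRates,
              network = network, disease = disease,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

validateSimulationConfig <- function(cfg) {
  with(cfg, {
    if (nProbes <= 0 || nGenes <= 0 || kTrue <= 0 || nEffect < 0)
      stop("all counts must be positive")
    if (any(groups$n <= 0)) stop("group sample sizes must be positive")
    if (nrow(meanProps) != nrow(groups) || ncol(meanProps) != kTrue)
      stop("meanProps must be groups x kTrue; kTrue inconsistent with ",
           "group proportion vectors")
    if (any(meanProps < 0 | meanProps > 1) ||
        any(abs(rowSums(meanProps) - 1) > 1e-8))
      stop("mixing proportions must lie in [0,1] and sum to 1 per group")
    if (length(deltaBeta) > 2 || any(deltaBeta <= 0 | deltaBeta >= 0.5))
      stop("effect deltaBeta must lie in (0, 0.5)")
    if (disease$overlapFraction < 0 || disease$overlapFraction >= 1)
      stop("overlap fraction must lie in [0, 1)")
    if (!disease$effectSign %in% c(-1, 1))
      stop("disease effect sign must be -1 or +1")
    if (network$moduleSize >= network$nNodes)
      stop("planted module size must be smaller than the network")
  })
  invisible(cfg)
}

#' Simulate latent cell-type methylomes
#'
#' Draws one base methylome from a three-state mixture (low /
#' intermediate / high methylation, the canonical bimodal-with-shoulder
#' shape of array betas) and, for each additional cell type, perturbs a
#' configurable fraction of probes by at least \code{minDiff} so cell
#' types are distinguishable; all other probes are shared exactly.
#' Entries are clipped to [0.01, 0.99].
#'
#' @param nProbes number of probes (>= 10).
#' @param kTrue number of cell types (>= 1).
#' @param seed integer seed.
#' @param diffFraction fraction of probes differing between cell types.
#' @param minDiff minimum absolute difference for a differing probe.
#' @return list with \code{mu} (nProbes x kTrue matrix) and
#'   \code{diffProbes} (indices of planted differing probes).
#' @export
simulateProfiles <- function(nProbes, kTrue, seed = 1L,
                             diffFraction = 0.3, minDiff = 0.2) {
  if (nProbes < 10 || kTrue < 1)
    stop("nProbes must be >= 10 and kTrue >= 1")
  withSeed(deriveSeed(seed, 11L), {
    state <- sample(1:3, nProbes, replace = TRUE, prob = c(0.4, 0.2, 0.4))
    base <- numeric(nProbes)
    base[state == 1] <- rbeta(sum(state == 1), 4, 20)    # low
    base[state == 2] <- rbeta(sum(state == 2), 10, 10)   # intermediate
    base[state == 3] <- rbeta(sum(state == 3), 20, 4)    # high
    base <- pmin(pmax(base, 0.01), 0.99)
    mu <- matrix(base, nProbes, kTrue)
    diffProbes <- integer(0)
    if (kTrue > 1 && diffFraction > 0) {
      nDiff <- floor(diffFraction * nProbes)
      diffProbes <- sort(sample.int(nProbes, nDiff))
      for (k in 2:kTrue) {
        b <- base[diffProbes]
        shift <- runif(nDiff, minDiff, min(minDiff + 0.2, 0.9))
        up <- b + shift <= 0.99
        val <- ifelse(up, b + shift, b - shift)
        val <- pmin(pmax(val, 0.01), 0.99)
        # direction with >= minDiff headroom always exists for b in [.01,.99]
        mu[diffProbes, k] <- val
      }
    }
    rownames(mu) <- sprintf("cg%07d", seq_len(nProbes))
    list(mu = mu, diffProbes = diffProbes)
  })
}

drawOmega <- function(meanProps, n, concentration) {
  k <- length(meanProps)
  g <- matrix(rgamma(n * k, shape = rep(meanProps, each = n) * concentration),
              n, k)
  sw <- rowSums(g)
  zero <- sw == 0
  if (any(zero)) { g[zero, ] <- 1; sw[zero] <- k }
  g / sw
}

assignGenes <- function(nProbes, nGenes, multiGeneFraction = 0.02) {
  per <- ceiling(nProbes / nGenes)
  gene1 <- sprintf("GENE%04d", rep(seq_len(nGenes), each = per)[seq_len(nProbes)])
  nMulti <- floor(multiGeneFraction * nProbes)
  gene <- gene1
  if (nMulti > 0) {
    idx <- sample.int(nProbes, nMulti)
    extra <- sprintf("GENE%04d", sample.int(nGenes, nMulti, replace = TRUE))
    keep <- extra != gene1[idx]
    gene[idx[keep]] <- paste(gene1[idx[keep]], extra[keep], sep = ";")
  }
  gene
}

#' Simulate a methylation cohort with ground truth
#'
#' Betas are drawn from a beta distribution around the per-sample mixture
#' mean \code{mu \%*\% omega_j}; planted group effects shift the
#' generating mean of the affected group by exactly the configured
#' delta-beta (applied as a per-observation logit-scale offset on
#' mid-range probes so no clipping occurs); QC artifacts are planted on
#' disjoint probe sets at the configured rates. The returned ground truth
#' records per-sample mixing proportions, the signed planted effects, the
#' probe-to-gene map and each filter's planted artifact probes.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{dataset} (a \linkS4class{MethylationSet}) and
#'   \code{truth} (list: \code{omega}, \code{mu}, \code{effects},
#'   \code{qc}, \code{probeGeneMap}, \code{profileDiffProbes}).
#' @export
simulateCohort <- function(config) {
  validateSimulationConfig(config)
  prof <- simulateProfiles(config$nProbes, config$kTrue, config$seed,
                           config$profileDiffFraction,
                           config$profileMinDiff)
  withSeed(deriveSeed(config$seed, 23L), {
    nTot <- sum(config$groups$n)
    groupVec <- rep(config$groups$label, config$groups$n)
    omega <- do.call(rbind, lapply(seq_len(nrow(config$groups)), function(g)
      drawOmega(config$meanProps[g, ], config$groups$n[g],
                config$omegaConcentration)))
    sampleIds <- sprintf("%s_%02d", groupVec, stats::ave(
      seq_len(nTot), groupVec, FUN = seq_along))
    rownames(omega) <- sampleIds

    mean0 <- prof$mu %*% t(omega)                 # probes x samples
    probeIds <- rownames(prof$mu)
    dimnames(mean0) <- list(probeIds, sampleIds)

    ## plant effects: T2 vs NP contrast, exact mean shift on eligible
    ## probes. Only composition-neutral probes (identical across cell
    ## types) are eligible so the planted delta-beta equals the
    ## expectation difference of the generating group means; mid-range
    ## means keep the shift clip-free.
    eligible <- which(apply(mean0, 1, function(m)
      all(m > 0.18 & m < 0.82)))
    eligible <- setdiff(eligible, prof$diffProbes)
    effects <- data.frame(probe = character(0), gene = character(0),
                          contrast = character(0), deltaBeta = numeric(0))
    gene <- assignGenes(config$nProbes, config$nGenes)
    meanMat <- mean0
    effIdx <- integer(0)
    if (config$nEffect > 0) {
      if (length(eligible) < config$nEffect)
        stop("not enough mid-range probes to plant the requested effects")
      effIdx <- sort(sample(eligible, config$nEffect))
      sign <- ifelse(runif(config$nEffect) < config$hyperFraction, 1, -1)
      mag <- if (length(config$deltaBeta) == 2)
        runif(config$nEffect, config$deltaBeta[1], config$deltaBeta[2])
      else rep(config$deltaBeta, config$nEffect)
      db <- sign * mag
      t2 <- which(groupVec == "T2")
      if (identical(config$effectCellType, "all")) {
        meanMat[effIdx, t2] <- meanMat[effIdx, t2] + db
        achieved <- db
      } else {
        k <- as.integer(config$effectCellType)
        stopifnot(k >= 1, k <= config$kTrue)
        muT2 <- prof$mu
        muT2[effIdx, k] <- pmin(pmax(muT2[effIdx, k] + db, 0.01), 0.99)
        meanMat[, t2] <- muT2 %*% t(omega[t2, , drop = FALSE])
        achieved <- rowMeans(muT2[effIdx, , drop = FALSE] %*%
                             t(omega[t2, , drop = FALSE]) -
                             mean0[effIdx, t2, drop = FALSE])
      }
      effects <- data.frame(probe = probeIds[effIdx],
                            gene = gene[effIdx],
                            contrast = "T2_vs_NP",
                            deltaBeta = achieved,
                            stringsAsFactors = FALSE)
    }

    ## observation noise
    nu <- config$noisePrecision
    if (is.infinite(nu)) {
      beta <- meanMat
    } else {
      beta <- matrix(rbeta(length(meanMat), meanMat * nu,
                           (1 - meanMat) * nu),
                     nrow(meanMat), ncol(meanMat), dimnames = dimnames(meanMat))
    }
    beta <- pmin(pmax(beta, 1e-4), 1 - 1e-4)

    ## QC artifacts on disjoint probe sets, never on effect probes
    rates <- config$qcArtifactRates
    pool <- setdiff(seq_len(config$nProbes), effIdx)
    qc <- list()
    for (f in c("detP", "bead", "noCpG", "snp", "multi")) {
      nArt <- floor(rates[[f]] * config$nProbes)
      pick <- if (nArt > 0) sort(sample(pool, nArt)) else integer(0)
      pool <- setdiff(pool, pick)
      qc[[f]] <- probeIds[pick]
    }

    detP <- matrix(runif(length(beta), 0, 0.009), nrow(beta), ncol(beta),
                   dimnames = dimnames(beta))
    if (length(qc$detP) > 0)
      detP[cbind(match(qc$detP, probeIds),
                 sample.int(nTot, length(qc$detP), replace = TRUE))] <-
        runif(length(qc$detP), 0.011, 0.05)

    probeInfo <- data.frame(
      gene = gene,
      chr = sample(paste0("chr", 1:22), config$nProbes, replace = TRUE),
      pos = sample.int(1e8, config$nProbes),
      strand = sample(c("+", "-"), config$nProbes, replace = TRUE),
      designType = sample(c("I", "II"), config$nProbes, replace = TRUE,
                          prob = c(0.2, 0.8)),
      minBeadCount = sample(5:30, config$nProbes, replace = TRUE),
      hasCpG = TRUE, nearSNP = FALSE, multiMap = FALSE,
      row.names = probeIds, stringsAsFactors = FALSE)
    probeInfo$minBeadCount[probeIds %in% qc$bead] <- 2L
    probeInfo$hasCpG[probeIds %in% qc$noCpG] <- FALSE
    probeInfo$nearSNP[probeIds %in% qc$snp] <- TRUE
    probeInfo$multiMap[probeIds %in% qc$multi] <- TRUE

    memCol <- min(2L, config$kTrue)
    sampleInfo <- data.frame(
      sampleId = sampleIds, group = groupVec, sex = "F",
      measuredMemory = pmin(pmax(omega[, memCol] +
                                 rnorm(nTot, 0, 0.03), 0), 1),
      stringsAsFactors = FALSE)

    ds <- MethylationSet(beta, sampleInfo, probeInfo, detP = detP)
    pgm <- probeGenes(ds)
    list(dataset = ds,
         truth = list(omega = omega, mu = prof$mu, effects = effects,
                      qc = qc, probeGeneMap = pgm,
                      profileDiffProbes = rownames(prof$mu)[prof$diffProbes],
                      groups = groupVec))
  })
}

## Preferential attachment: start from one edge between nodes 1-2; each
## subsequent node attaches min(m, existing) distinct targets sampled
## proportionally to current degree. Edge count for m <= 2 is
## 1 + m * (n - 2).
prefAttachEdges <- function(n, m) {
  stopifnot(n >= 2, m >= 1)
  deg <- integer(n)
  from <- integer(0); to <- integer(0)
  deg[1:2] <- 1L; from <- 1L; to <- 2L
  for (v in 3:n) {
    nt <- min(m, v - 1L)
    targets <- sample.int(v - 1L, nt, prob = deg[seq_len(v - 1L)])
    from <- c(from, rep.int(v, nt)); to <- c(to, targets)
    deg[targets] <- deg[targets] + 1L
    deg[v] <- nt
  }
  cbind(from, to)
}

#' Simulate a scored scale-free interaction network with a planted module
#'
#' Background topology is preferential attachment (connected, scale-free
#' degree distribution); a dense module (by default a clique) is planted
#' on genes drawn from the supplied effect genes so that the module is
#' enriched among them. Beyond the clique, a configurable number of
#' extra edges is added between random pairs of effect genes
#' (\code{coLocalizeEffects} times the effect gene count), emulating the
#' broad network co-localization of condition-associated genes that the
#' seed-distance permutation test measures. All emitted combined scores
#' are at or above the configured threshold; planted-module edges get
#' the highest scores.
#'
#' @param config a \code{\link{simulationConfig}} (its \code{network}
#'   block is used).
#' @param effectGenes character vector of effect (seed) gene symbols the
#'   planted module should be drawn from; \code{NULL} for random genes.
#' @param plantModule logical; set \code{FALSE} to emit the bare
#'   background graph.
#' @param seed integer seed (defaults to the config master seed).
#' @return list with \code{network} (a \linkS4class{PPINetwork}) and
#'   \code{truth} (list with \code{moduleGenes}).
#' @export
simulateNetwork <- function(config, effectGenes = NULL, plantModule = TRUE,
                            seed = config$seed) {
  net <- config$network
  if (net$moduleSize < 3) stop("planted module size must be >= 3")
  if (net$moduleSize >= net$nNodes)
    stop("planted module size must be smaller than the network")
  withSeed(deriveSeed(seed, 37L), {
    nodes <- sprintf("GENE%04d", seq_len(net$nNodes))
    el <- prefAttachEdges(net$nNodes, net$m)
    edges <- data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]],
                        score = sample(net$minScore:960, nrow(el),
                                       replace = TRUE),
                        stringsAsFactors = FALSE)
    moduleGenes <- character(0)
    if (plantModule) {
      pool <- if (is.null(effectGenes)) nodes else
        intersect(unique(effectGenes), nodes)
      if (length(pool) < net$moduleSize)
        pool <- union(pool, sample(setdiff(nodes, pool),
                                   net$moduleSize - length(pool)))
      moduleGenes <- sort(sample(pool, net$moduleSize))
      cl <- t(utils::combn(moduleGenes, 2))
      edges <- rbind(edges,
                     data.frame(from = cl[, 1], to = cl[, 2], score = 990,
                                stringsAsFactors = FALSE))
      nExtra <- round(net$coLocalizeEffects * length(pool))
      if (nExtra > 0 && length(pool) >= 4) {
        p1 <- sample(pool, nExtra, replace = TRUE)
        p2 <- sample(pool, nExtra, replace = TRUE)
        keep <- p1 != p2
        edges <- rbind(edges, data.frame(
          from = p1[keep], to = p2[keep],
          score = sample(net$minScore:960, sum(keep), replace = TRUE),
          stringsAsFactors = FALSE))
      }
    }
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
    network <- methods::new("PPINetwork", graph = g,
                            minScore = as.numeric(net$minScore))
    list(network = network, truth = list(moduleGenes = moduleGenes))
  })
}

#' Simulate a disease case/control cohort tied to pregnancy ground truth
#'
#' Case effects are planted on a configurable subset of the pregnancy
#' effect probes with sign \code{effectSign} times the pregnancy sign; a
#' floor(overlapFraction * nControls)-sized subgroup of controls receives
#' case-like generating means (the non-separable subgroup the divisive
#' selection step is meant to remove). Ground truth flags exactly those
#' controls and records the signed disease effects.
#'
#' @param config a \code{\link{simulationConfig}} (its \code{disease}
#'   block is used).
#' @param pregnancyTruth the \code{truth} component returned by
#'   \code{\link{simulateCohort}}.
#' @param seed integer seed (defaults to the config master seed).
#' @return list with \code{dataset} and \code{truth} (\code{effects},
#'   \code{overlapControls}, \code{omega}, \code{diseaseGenes}).
#' @export
simulateDiseaseCohort <- function(config, pregnancyTruth,
                                  seed = config$seed) {
  dz <- config$disease
  if (dz$overlapFraction >= 1) stop("overlap fraction must be < 1")
  if (!dz$effectSign %in% c(-1, 1)) stop("effect sign must be -1 or +1")
  preg <- pregnancyTruth$effects
  if (nrow(preg) == 0) stop("pregnancy truth provides no effect probes")
  withSeed(deriveSeed(seed, 53L), {
    mu <- pregnancyTruth$mu
    probeIds <- rownames(mu)
    n <- dz$nCases + dz$nControls
    groupVec <- rep(c("case", "control"), c(dz$nCases, dz$nControls))
    sampleIds <- sprintf("D%s_%02d", ifelse(groupVec == "case", "C", "H"),
                         stats::ave(seq_len(n), groupVec, FUN = seq_along))
    omega <- drawOmega(dz$meanProps, n, config$omegaConcentration)
    rownames(omega) <- sampleIds
    meanMat <- mu %*% t(omega)
    dimnames(meanMat) <- list(probeIds, sampleIds)

    nShared <- max(3L, floor(dz$sharedFraction * nrow(preg)))
    nShared <- min(nShared, nrow(preg))
    shared <- preg[seq_len(nShared), , drop = FALSE]
    ## disease magnitude inherits the pregnancy magnitude per probe
    ## unless a constant is configured; the sign is relative
    db <- if (is.null(dz$deltaBeta)) dz$effectSign * shared$deltaBeta
          else dz$effectSign * sign(shared$deltaBeta) * dz$deltaBeta

    nOver <- floor(dz$overlapFraction * dz$nControls)
    ctrlIds <- sampleIds[groupVec == "control"]
    overlapControls <- if (nOver > 0) sort(sample(ctrlIds, nOver))
                       else character(0)
    affected <- c(sampleIds[groupVec == "case"], overlapControls)

    ridx <- match(shared$probe, probeIds)
    cidx <- match(affected, sampleIds)
    meanMat[ridx, cidx] <- pmin(pmax(meanMat[ridx, cidx] + db, 0.02), 0.98)

    nu <- config$noisePrecision
    if (is.infinite(nu)) beta <- meanMat
    else beta <- matrix(rbeta(length(meanMat), meanMat * nu,
                              (1 - meanMat) * nu),
                        nrow(meanMat), ncol(meanMat),
                        dimnames = dimnames(meanMat))
    beta <- pmin(pmax(beta, 1e-4), 1 - 1e-4)

    pg <- split(pregnancyTruth$probeGeneMap$gene,
                pregnancyTruth$probeGeneMap$probe)
    probeInfo <- data.frame(
      gene = vapply(probeIds, function(p) {
        g <- pg[[p]]
        if (is.null(g)) "" else paste(g, collapse = ";")
      }, ""),
      designType = "II", minBeadCount = 10L, hasCpG = TRUE,
      nearSNP = FALSE, multiMap = FALSE,
      row.names = probeIds, stringsAsFactors = FALSE)
    sampleInfo <- data.frame(sampleId = sampleIds, group = groupVec,
                             sex = "F", stringsAsFactors = FALSE)
    ds <- MethylationSet(beta, sampleInfo, probeInfo)
    effects <- data.frame(probe = shared$probe, gene = shared$gene,
                          contrast = "case_vs_control", deltaBeta = db,
                          pregnancyDeltaBeta = shared$deltaBeta,
                          stringsAsFactors = FALSE)
    diseaseGenes <- sort(unique(unlist(strsplit(shared$gene, ";"))))
    list(dataset = ds,
         truth = list(effects = effects,
                      overlapControls = overlapControls,
                      omega = omega, diseaseGenes = diseaseGenes))
  })
}
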