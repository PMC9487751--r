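## One-sided (enrichment) Fisher tail, identical to fisher.test with
## alternative = "greater" on the 2x2 (a, setSize-a; drawSize-a, rest).
hyperTailP <- function(a, setSize, drawSize, N) {
  phyper(a - 1, setSize, N - setSize, drawSize, lower.tail = FALSE)
}

mcodeVertexWeights <- function(g) {
  vapply(seq_len(igraph::vcount(g)), function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0) return(0)
    kc <- igraph::induced_subgraph(sub, which(core >= kmax))
    dens <- igraph::edge_density(kc)
    if (!is.finite(dens)) dens <- 0
    kmax * dens
  }, 0)
}

#' MCODE complex detection
#'
#' Bader-Hogue molecular complex detection: each vertex is weighted by
#' the core number of the highest k-core of its open neighbourhood times
#' that k-core's density; complexes are grown outward from the
#' highest-weight unused vertex, admitting neighbours whose weight is at
#' least (1 - vwp) of the seed vertex weight; a haircut iteratively
#' removes singly-connected vertices (fluff is off). Complexes are
#' scored by density x size; the returned module is the union of
#' complexes at or above \code{minComplexScore} that contain at least
#' one supplied seed gene.
#'
#' @param network a \linkS4class{PPINetwork}.
#' @param seeds seed gene symbols (module anchors; non-seed genes may
#'   appear in the output).
#' @param vwp vertex weight percentage (default 0.2).
#' @param minComplexScore complex score cutoff (default 0 = keep all
#'   seed-containing complexes).
#' @param haircut iteratively trim degree-1 vertices (default TRUE).
#' @return a \linkS4class{ModuleResult}.
#' @export
runMcode <- function(network, seeds, vwp = 0.2, minComplexScore = 0,
                     haircut = TRUE) {
  g <- network@graph
  if (igraph::vcount(g) == 0) stop("empty network")
  w <- mcodeVertexWeights(g)
  n <- igraph::vcount(g)
  used <- rep(FALSE, n)
  complexes <- list()
  adj <- igraph::adjacent_vertices(g, seq_len(n))
  for (v in order(w, decreasing = TRUE)) {
    if (used[v] || w[v] <= 0) next
    thresh <- (1 - vwp) * w[v]
    members <- v; used[v] <- TRUE
    queue <- v
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (nb in as.integer(adj[[u]])) {
        if (!used[nb] && w[nb] >= thresh) {
          used[nb] <- TRUE
          members <- c(members, nb)
          queue <- c(queue, nb)
        }
      }
    }
    if (haircut && length(members) >= 3) {
      repeat {
        sub <- igraph::induced_subgraph(g, members)
        deg <- igraph::degree(sub)
        if (all(deg >= 2) || length(members) < 3) break
        members <- members[deg >= 2]
        if (length(members) == 0) break
      }
    }
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(g, members)
    dens <- igraph::edge_density(sub)
    if (!is.finite(dens)) dens <- 0
    complexes[[length(complexes) + 1]] <-
      list(members = igraph::V(g)$name[members],
           score = dens * length(members))
  }
  seeds <- intersect(seeds, igraph::V(g)$name)
  keep <- Filter(function(cx)
    cx$score >= minComplexScore && length(intersect(cx$members, seeds)) > 0,
    complexes)
  genes <- sort(unique(unlist(lapply(keep, `[[`, "members"))))
  methods::new("ModuleResult", method = "mcode",
               genes = as.character(genes),
               scores = setNames(w[match(genes, igraph::V(g)$name)],
                                 genes),
               seeds = seeds,
               parameters = list(vwp = vwp,
                                 minComplexScore = minComplexScore,
                                 haircut = haircut,
                                 complexes = keep))
}

#' DIAMOnD disease-module expansion
#'
#' Iteratively adds the candidate node with the most significant
#' connectivity to the current member set: for a node of degree k with
#' ks links into the s members of an N-node network, the significance is
#' the hypergeometric tail P(X >= ks). Seed links can be up-weighted by
#' \code{alpha}. Ties are broken by higher ks, then lower degree, then
#' lexicographic node id. The module is the seeds present in the network
#' plus the added nodes in order.
#'
#' @param network a \linkS4class{PPINetwork}.
#' @param seeds seed gene symbols (>= 1 mapped).
#' @param nAdded number of nodes to add (>= 1).
#' @param alpha seed link weight (default 1 = unweighted).
#' @return a \linkS4class{ModuleResult}; \code{scores} holds the
#'   per-added-gene rank; the p-value sequence is in
#'   \code{parameters$pSequence}.
#' @export
runDiamond <- function(network, seeds, nAdded = 200L, alpha = 1) {
  g <- network@graph
  nodes <- igraph::V(g)$name
  seedsIn <- intersect(seeds, nodes)
  if (length(seedsIn) == 0) stop("no seed genes present in the network")
  if (nAdded < 1) stop("nAdded must be >= 1")
  N0 <- length(nodes)
  deg <- igraph::degree(g)
  adjList <- lapply(igraph::adjacent_vertices(g, seq_along(nodes)),
                    as.integer)
  inSet <- nodes %in% seedsIn
  isSeed <- inSet
  added <- character(0); pSeq <- numeric(0)
  for (step in seq_len(nAdded)) {
    memberIdx <- which(inSet)
    cand <- setdiff(unique(unlist(adjList[memberIdx])), memberIdx)
    if (length(cand) == 0) break
    ks <- vapply(cand, function(v) sum(inSet[adjList[[v]]]), 0L)
    ksSeed <- vapply(cand, function(v) sum(isSeed[adjList[[v]]]), 0L)
    k <- deg[cand]
    sN <- sum(inSet); nSeedIn <- sum(isSeed & inSet)
    ksA <- ks + (alpha - 1) * ksSeed
    kA <- k + (alpha - 1) * ksSeed
    sA <- sN + (alpha - 1) * nSeedIn
    NA_ <- N0 + (alpha - 1) * nSeedIn
    p <- hyperTailP(ksA, sA, kA, NA_)
    ord <- order(p, -ksA, kA, nodes[cand])
    pick <- cand[ord[1]]
    inSet[pick] <- TRUE
    added <- c(added, nodes[pick])
    pSeq <- c(pSeq, p[ord[1]])
  }
  genes <- c(seedsIn, added)
  ranks <- c(rep(0, length(seedsIn)), seq_along(added))
  methods::new("ModuleResult", method = "diamond", genes = genes,
               scores = setNames(ranks, genes), seeds = seedsIn,
               parameters = list(nAdded = nAdded, alpha = alpha,
                                 pSequence = pSeq, added = added))
}

#' Clique Sum module detection
#'
#' Enumerates maximal cliques of at least \code{minCliqueSize} nodes and
#' keeps those whose seed content is significant by the one-sided Fisher
#' exact (hypergeometric tail) test after Bonferroni correction over the
#' tested cliques; the module is the union of kept cliques.
#'
#' @param network a \linkS4class{PPINetwork}.
#' @param seeds seed gene symbols.
#' @param minCliqueSize smallest clique size enumerated (default 3).
#' @param alpha Bonferroni-corrected significance level (default 0.05).
#' @param maxCliques enumeration budget; exceeding it is an error
#'   advising a higher score threshold.
#' @return a \linkS4class{ModuleResult}.
#' @export
runCliqueSum <- function(network, seeds, minCliqueSize = 3L,
                         alpha = 0.05, maxCliques = 200000L) {
  g <- network@graph
  nC <- igraph::count_max_cliques(g, min = minCliqueSize)
  if (nC > maxCliques)
    stop("maximal-clique count ", nC, " exceeds the budget (",
         maxCliques, "); raise the edge score threshold")
  cliques <- igraph::max_cliques(g, min = minCliqueSize)
  nodes <- igraph::V(g)$name
  seeds <- intersect(seeds, nodes)
  N <- length(nodes); nSeeds <- length(seeds)
  kept <- list(); pKept <- numeric(0)
  m <- length(cliques)
  for (cl in cliques) {
    mem <- nodes[as.integer(cl)]
    a <- length(intersect(mem, seeds))
    if (a == 0) next
    p <- hyperTailP(a, nSeeds, length(mem), N)
    if (m * p < alpha) {
      kept[[length(kept) + 1]] <- mem
      pKept <- c(pKept, p)
    }
  }
  genes <- sort(unique(unlist(kept)))
  if (is.null(genes)) genes <- character(0)
  methods::new("ModuleResult", method = "clique_sum",
               genes = as.character(genes),
               scores = setNames(rep(NA_real_, length(genes)), genes),
               seeds = seeds,
               parameters = list(minCliqueSize = minCliqueSize,
                                 alpha = alpha, nCliquesTested = m,
                                 keptCliques = kept, keptP = pKept))
}

#' Correlation Clique module detection
#'
#' Stochastic consensus clique search: in each iteration every edge is
#' retained independently with probability (edge score / 1000) times the
#' mean seed-score factor of its endpoints (non-seeds contribute the
#' \code{baseline} factor); maximal cliques of the sampled graph are
#' tested for seed enrichment (one-sided Fisher, p < alpha), and genes
#' in any passing clique are marked present for that iteration. The
#' module is the set of genes present in at least \code{freqCutoff} of
#' iterations. The edge-probability formula is a documented
#' reconstruction with all constants exposed.
#'
#' @param network a \linkS4class{PPINetwork}.
#' @param seeds seed gene symbols.
#' @param seedScores named significance weights in (0, 1] for the seeds
#'   (default: all 1).
#' @param nIter iterations (>= 2).
#' @param freqCutoff inclusion frequency threshold (default 0.5).
#' @param alpha per-clique enrichment significance level.
#' @param baseline non-seed node factor in the edge probability.
#' @param minCliqueSize smallest clique considered.
#' @param rngSeed integer seed.
#' @return a \linkS4class{ModuleResult}; \code{scores} holds inclusion
#'   frequencies.
#' @export
runCorrelationClique <- function(network, seeds, seedScores = NULL,
                                 nIter = 50L, freqCutoff = 0.5,
                                 alpha = 0.05, baseline = 0.5,
                                 minCliqueSize = 3L, rngSeed = 1L) {
  if (nIter < 2) stop("nIter must be >= 2")
  g <- network@graph
  nodes <- igraph::V(g)$name
  seeds <- intersect(seeds, nodes)
  if (is.null(seedScores)) seedScores <- setNames(rep(1, length(seeds)),
                                                  seeds)
  if (any(seedScores <= 0 | seedScores > 1))
    stop("seed scores must lie in (0, 1]")
  factorOf <- setNames(rep(baseline, length(nodes)), nodes)
  factorOf[names(seedScores)[names(seedScores) %in% nodes]] <-
    seedScores[names(seedScores) %in% nodes]
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  pEdge <- (igraph::E(g)$score / 1000) *
    (factorOf[ends[, 1]] + factorOf[ends[, 2]]) / 2
  pEdge <- pmin(pmax(pEdge, 0), 1)
  N <- length(nodes); nSeeds <- length(seeds)
  present <- setNames(numeric(length(nodes)), nodes)
  withSeed(deriveSeed(rngSeed, 83L), {
    for (it in seq_len(nIter)) {
      keep <- runif(length(pEdge)) < pEdge
      sg <- igraph::subgraph_from_edges(g, which(keep),
                                        delete.vertices = FALSE)
      cls <- igraph::max_cliques(sg, min = minCliqueSize)
      hit <- character(0)
      for (cl in cls) {
        mem <- nodes[as.integer(cl)]
        a <- length(intersect(mem, seeds))
        if (a == 0) next
        if (hyperTailP(a, nSeeds, length(mem), N) < alpha)
          hit <- union(hit, mem)
      }
      present[hit] <- present[hit] + 1
    }
  })
  freq <- present / nIter
  genes <- sort(names(freq)[freq >= freqCutoff])
  methods::new("ModuleResult", method = "correlation_clique",
               genes = genes, scores = freq[genes], seeds = seeds,
               parameters = list(nIter = nIter, freqCutoff = freqCutoff,
                                 alpha = alpha, baseline = baseline,
                                 frequencies = freq))
}

#' Consensus module across the four detection methods
#'
#' A gene enters the consensus iff it is a member of at least
#' \code{minMethods} of the supplied method modules. Per-gene
#' method-membership booleans, a seed (DMG) origin flag and, where
#' supplied, the methylation direction of seed-origin genes are
#' attached.
#'
#' @param results list of exactly 4 \linkS4class{ModuleResult}s with
#'   distinct method names.
#' @param minMethods membership threshold (default 3).
#' @param dmgDirections optional named character ("hyper"/"hypo") by
#'   gene.
#' @return a \linkS4class{ConsensusModule}.
#' @export
buildConsensus <- function(results, minMethods = 3L,
                           dmgDirections = NULL) {
  methodsUsed <- vapply(results, function(r) r@method, "")
  if (length(results) != 4)
    stop("exactly 4 module results are required")
  if (anyDuplicated(methodsUsed))
    stop("duplicate method names: ",
         paste(methodsUsed[duplicated(methodsUsed)], collapse = ", "))
  allGenes <- sort(unique(unlist(lapply(results, function(r) r@genes))))
  membership <- vapply(results, function(r) allGenes %in% r@genes,
                       logical(length(allGenes)))
  membership <- matrix(membership, nrow = length(allGenes),
                       dimnames = list(allGenes, methodsUsed))
  keep <- rowSums(membership) >= minMethods
  genes <- allGenes[keep]
  seedsAll <- unique(unlist(lapply(results, function(r) r@seeds)))
  seedOrigin <- genes %in% seedsAll
  direction <- rep(NA_character_, length(genes))
  if (!is.null(dmgDirections)) {
    i <- match(genes, names(dmgDirections))
    direction[!is.na(i)] <- unname(dmgDirections[i[!is.na(i)]])
  }
  methods::new("ConsensusModule", genes = genes,
               membership = membership[keep, , drop = FALSE],
               minMethods = as.integer(minMethods),
               seedOrigin = seedOrigin, direction = direction)
}

#' Project a gene module to its measured CpGs
#'
#' Returns every measured CpG mapping to a module gene, carrying the
#' requested contrast's delta-beta and DMP status from the supplied DMP
#' table. Module genes absent from the annotation are skipped with a
#' warning.
#'
#' @param module a \linkS4class{ConsensusModule} (or character gene
#'   vector).
#' @param annotation probe -> gene long table (\code{probe},
#'   \code{gene}).
#' @param dmpTable DMP table (\code{\link{callDmps}} output).
#' @param contrast contrast label to extract (default "T2_vs_NP").
#' @return data.frame: \code{probe}, \code{gene}, \code{deltaBeta},
#'   \code{q}, \code{isDMP}.
#' @export
moduleToCpgs <- function(module, annotation, dmpTable,
                         contrast = "T2_vs_NP") {
  genes <- if (methods::is(module, "ConsensusModule")) module@genes
           else as.character(module)
  missing <- setdiff(genes, annotation$gene)
  if (length(missing) > 0)
    warning("module gene(s) without annotated probes skipped: ",
            paste(missing, collapse = ", "))
  ann <- annotation[annotation$gene %in% genes, , drop = FALSE]
  dt <- dmpTable[dmpTable$contrast == contrast, , drop = FALSE]
  out <- merge(ann, dt[, c("probe", "deltaBeta", "q", "isDMP")],
               by = "probe")
  out[order(out$gene, out$probe), ]
}
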