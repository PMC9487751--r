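# Independent brute-force oracles used to cross-check the graph and
# enrichment machinery. Deliberately naive implementations that share no
# code with the package internals.

# plain BFS all-pairs shortest paths on an adjacency list
bfsDistanceOracle <- function(adj, from) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[from] <- 0
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

harmonicOracle <- function(edgeMat, n, seedIdx) {
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(edgeMat))) {
    a <- edgeMat[r, 1]; b <- edgeMat[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  tot <- 0; np <- 0
  for (i in seq_along(seedIdx)) {
    di <- bfsDistanceOracle(adj, seedIdx[i])
    for (j in seq_along(seedIdx)) {
      if (j <= i) next
      d <- di[seedIdx[j]]
      np <- np + 1
      if (is.finite(d) && d > 0) tot <- tot + 1 / d
    }
  }
  np / tot
}

# enumerate ALL cliques recursively, then keep the maximal ones
maximalCliqueOracle <- function(adjMat, minSize = 3) {
  n <- nrow(adjMat)
  cliques <- list()
  extend <- function(cur) {
    cliques[[length(cliques) + 1]] <<- cur
    last <- if (length(cur) > 0) max(cur) else 0
    for (v in seq_len(n)) {
      if (v <= last) next
      if (all(adjMat[cur, v] == 1)) extend(c(cur, v))
    }
  }
  for (v in seq_len(n)) extend(v)
  keep <- vapply(cliques, function(cl) {
    length(cl) >= minSize &&
      !any(vapply(cliques, function(other)
        length(other) > length(cl) && all(cl %in% other), TRUE))
  }, TRUE)
  lapply(cliques[keep], sort)
}

# exhaustive hypergeometric re-computation of the DIAMOnD ranking
diamondOracle <- function(adjMat, nodeNames, seedNames, nAdded) {
  n <- nrow(adjMat)
  hyperP <- function(ks, s, k, N) {
    # P(X >= ks), X ~ Hypergeometric(s successes, N-s failures, k draws)
    tot <- 0
    for (i in ks:min(k, s))
      tot <- tot + choose(s, i) * choose(N - s, k - i)
    tot / choose(N, k)
  }
  inSet <- nodeNames %in% seedNames
  added <- character(0)
  for (step in seq_len(nAdded)) {
    cand <- which(!inSet & (adjMat %*% inSet)[, 1] > 0)
    if (length(cand) == 0) break
    s <- sum(inSet)
    stats <- t(vapply(cand, function(v) {
      ks <- sum(adjMat[v, ] & inSet)
      k <- sum(adjMat[v, ])
      c(p = hyperP(ks, s, k, n), ks = ks, k = k)
    }, c(0, 0, 0)))
    ord <- order(stats[, "p"], -stats[, "ks"], stats[, "k"],
                 nodeNames[cand])
    pick <- cand[ord[1]]
    inSet[pick] <- TRUE
    added <- c(added, nodeNames[pick])
  }
  added
}

# two-sided Fisher p by explicit enumeration of tables with fixed margins
fisherOracle <- function(a, b, c, d) {
  N <- a + b + c + d
  qs <- a + b     # query size
  ts <- a + c     # target size
  lo <- max(0, qs + ts - N); hi <- min(qs, ts)
  probs <- vapply(lo:hi, function(x) dhyper(x, ts, N - ts, qs), 0)
  obs <- dhyper(a, ts, N - ts, qs)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

randomGraph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) { adj[i, j] <- 1L; adj[j, i] <- 1L }
  }
  adj
}

graphFromAdj <- function(adjMat, score = 950) {
  idx <- which(adjMat == 1 & upper.tri(adjMat), arr.ind = TRUE)
  nodes <- sprintf("n%02d", seq_len(nrow(adjMat)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
               score = score),
    directed = FALSE, vertices = nodes)
  methods::new("PPINetwork", graph = g, minScore = 900)
}
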