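## Exact box-constrained least squares for all probes at once.
## The design (omega, samples x K) is shared across probes, so each
## active-set pattern in {free, at 0, at 1}^K needs one shared solve;
## per probe the feasible candidate with smallest RSS is kept. Exact for
## small K (3^K patterns), which is the regime of cell-type mixtures.
boundedLSAll <- function(B, omega) {
  K <- ncol(omega); nP <- ncol(B)
  patterns <- as.matrix(expand.grid(rep(list(0:2), K)))  # 0 free, 1 at0, 2 at1
  bestRSS <- rep(Inf, nP)
  bestM <- matrix(0, K, nP)
  OtO <- crossprod(omega)
  OtB <- crossprod(omega, B)
  BtB <- colSums(B * B)
  for (r in seq_len(nrow(patterns))) {
    pat <- patterns[r, ]
    Fr <- which(pat == 0); at1 <- which(pat == 2)
    M <- matrix(0, K, nP)
    if (length(at1) > 0) M[at1, ] <- 1
    if (length(Fr) > 0) {
      rhs <- OtB[Fr, , drop = FALSE]
      if (length(at1) > 0)
        rhs <- rhs - OtO[Fr, at1, drop = FALSE] %*% M[at1, , drop = FALSE]
      A <- OtO[Fr, Fr, drop = FALSE]
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      M[Fr, ] <- sol
      feas <- colSums(sol < -1e-10 | sol > 1 + 1e-10) == 0
    } else feas <- rep(TRUE, nP)
    if (!any(feas)) next
    ## rss via cross-products: ||b||^2 - 2 m'O'b + m'O'O m
    rss <- BtB - 2 * colSums(M * OtB) + colSums(M * (OtO %*% M))
    upd <- feas & rss < bestRSS - 1e-12
    bestRSS[upd] <- rss[upd]
    bestM[, upd] <- pmin(pmax(M[, upd, drop = FALSE], 0), 1)
  }
  t(bestM)                                  # probes x K
}

## Exact simplex-constrained least squares for all samples at once.
## Enumerates zero-sets; equality constraint handled by a Lagrange
## multiplier, shared solve across samples.
simplexLSAll <- function(B, mu) {
  K <- ncol(mu); nS <- ncol(B)
  MtM <- crossprod(mu)
  MtB <- crossprod(mu, B)
  BtB <- colSums(B * B)
  bestRSS <- rep(Inf, nS)
  bestW <- matrix(0, K, nS)
  subsets <- lapply(seq_len(2^K - 1), function(code)
    which(bitwAnd(code, 2^(seq_len(K) - 1)) > 0))
  for (Fr in subsets) {
    A <- MtM[Fr, Fr, drop = FALSE]
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv)) next
    C <- MtB[Fr, , drop = FALSE]
    one <- rep(1, length(Fr))
    Ai1 <- Ainv %*% one
    denom <- sum(one * Ai1)
    if (abs(denom) < 1e-12) next
    AiC <- Ainv %*% C
    lambda <- (1 - colSums(AiC)) / denom
    Wf <- AiC + Ai1 %*% t(lambda)
    feas <- colSums(Wf < -1e-10) == 0
    if (!any(feas)) next
    W <- matrix(0, K, nS)
    W[Fr, ] <- Wf
    rss <- BtB - 2 * colSums(W * MtB) + colSums(W * (MtM %*% W))
    upd <- feas & rss < bestRSS - 1e-12
    bestRSS[upd] <- rss[upd]
    bestW[, upd] <- pmax(W[, upd, drop = FALSE], 0)
  }
  W <- t(bestW)
  W / rowSums(W)
}

## Canonical form for the mixing ambiguity. Any invertible remix of the
## factor pair (mu columns i/j, omega columns i/j) that keeps omega rows
## on the simplex and mu in [0,1] leaves the fit unchanged, so the
## factorization is only identified up to that family. The convention
## adopted here anchors the solution at the extreme-profile endpoint:
## profiles are stretched apart until they (at the q-quantile, default
## the exact extreme, over probes with a meaningful difference) touch
## the [0,1] bounds --
## the standard anchor assumption that each cell type is essentially
## unmethylated/methylated at its distinguishing CpGs. Solved exactly as
## a 2-variable linear program per column pair.
canonicalizeMixing <- function(mu, omega, q = 0, dmin = 0.05) {
  K <- ncol(mu)
  pairs <- if (K < 2) list() else utils::combn(K, 2, simplify = FALSE)
  for (sweep in seq_len(if (K > 2) 2 else 1)) for (pr in pairs) {
    i <- pr[1]; j <- pr[2]
    d <- mu[, i] - mu[, j]
    s <- omega[, i] + omega[, j]
    sel <- abs(d) >= dmin
    if (sum(sel) < 20) next
    d2 <- d[sel]; m2 <- mu[sel, j]
    pos <- d2 > 0; neg <- d2 < 0
    gammaUB <- c(if (any(pos)) m2[pos] / d2[pos],
                 if (any(neg)) (1 - m2[neg]) / (-d2[neg]))
    stepUB <- c(if (any(pos)) (1 - m2[pos]) / d2[pos],
                if (any(neg)) m2[neg] / (-d2[neg]))
    gam <- quantile(gammaUB, q, names = FALSE)
    u <- gam + quantile(stepUB, q, names = FALSE)
    if (!is.finite(u) || u <= 0) next
    alpha <- 1 / u; beta <- gam * alpha
    wi <- pmin(pmax(alpha * omega[, i] + beta * s, 0), s)
    omega[, i] <- wi; omega[, j] <- s - wi
    muJ <- mu[, j] - gam * d
    mu[, j] <- pmin(pmax(muJ, 0), 1)
    mu[, i] <- pmin(pmax(muJ + d * u, 0), 1)
  }
  list(mu = mu, omega = omega)
}

#' Reference-free cell-type deconvolution by constrained NMF
#'
#' Factorizes a probes x samples beta matrix into K latent cell-type
#' methylomes (entries in [0,1]) and per-sample mixing proportions
#' (simplex rows) by alternating exact constrained least squares: mu
#' given omega by box-constrained LS, omega given mu by
#' simplex-constrained LS. Both block updates are exact, so the residual
#' sum of squares (the deviance) is non-increasing per outer iteration.
#' Several random restarts are run and the lowest-deviance fit kept.
#'
#' Because any simplex-preserving remix of the factors fits equally
#' well, the returned solution is put in a canonical form (unless
#' \code{canonical = FALSE}): profiles are stretched to the
#' extreme-profile endpoint of the equivalence family, reflecting the
#' anchor assumption that each cell type is essentially
#' unmethylated/methylated at its distinguishing CpGs. The transform
#' preserves the fit; a final proportion update re-polishes the
#' solution.
#'
#' @param betas probes x samples matrix in [0,1] (or a
#'   \linkS4class{MethylationSet}).
#' @param k number of latent cell types (1 <= k <= samples).
#' @param seed integer seed for the restarts.
#' @param maxIter outer-iteration cap.
#' @param tol relative deviance-change stopping tolerance.
#' @param nRestarts random restarts (lowest deviance kept).
#' @param canonical apply the extreme-profile identifiability
#'   convention (default TRUE).
#' @return a \linkS4class{MixtureDecomposition}.
#' @export
refFreeDecompose <- function(betas, k, seed = 1L, maxIter = 100L,
                             tol = 1e-6, nRestarts = 5L,
                             canonical = TRUE) {
  if (methods::is(betas, "MethylationSet")) betas <- betaValues(betas)
  B <- as.matrix(betas)
  stopIfNot01(B, "betas")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k > ncol(B)) stop("k must not exceed the number of samples")
  if (k > 1 && stats::sd(B) < 1e-12)
    warning("all-constant matrix with k > 1: profiles are duplicated")
  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- withSeed(deriveSeed(seed, 101L + r), {
      omega <- drawOmega(rep(1 / k, k), ncol(B), 1)
      trace <- numeric(0)
      dev0 <- Inf; converged <- FALSE; it <- 0L
      mu <- NULL
      tB <- t(B)
      for (it in seq_len(maxIter)) {
        mu <- boundedLSAll(tB, omega)
        omega <- simplexLSAll(B, mu)
        R <- B - mu %*% t(omega)
        dev <- sum(R * R)
        trace <- c(trace, dev)
        if (is.finite(dev0) &&
            (dev0 - dev) < tol * (1 + dev0)) { converged <- TRUE; break }
        dev0 <- dev
      }
      list(mu = mu, omega = omega, dev = dev, trace = trace,
           nIter = it, converged = converged)
    })
    if (is.null(best) || fit$dev < best$dev) best <- fit
  }
  if (canonical && k > 1) {
    cf <- canonicalizeMixing(best$mu, best$omega)
    cf$omega <- simplexLSAll(B, cf$mu)
    R <- B - cf$mu %*% t(cf$omega)
    best$mu <- cf$mu; best$omega <- cf$omega; best$dev <- sum(R * R)
  }
  dimnames(best$mu) <- list(rownames(B), paste0("type", seq_len(k)))
  dimnames(best$omega) <- list(colnames(B), paste0("type", seq_len(k)))
  methods::new("MixtureDecomposition", mu = best$mu, omega = best$omega,
               k = k, deviance = best$dev, trace = best$trace,
               nIter = best$nIter, converged = best$converged,
               seed = as.integer(seed))
}

#' Accessors for MixtureDecomposition
#' @param x a \linkS4class{MixtureDecomposition}.
#' @return the corresponding slot.
#' @export
cellProportions <- function(x) x@omega

#' @rdname cellProportions
#' @export
cellProfiles <- function(x) x@mu

#' @rdname cellProportions
#' @export
decompositionDeviance <- function(x) x@deviance

## Compact ALS refit used inside the bootstrap: a couple of random
## restarts, capped iterations, returns the profiled normal deviance
## n * sum_i log(rss_i / n) (per-probe variance profiled out).
bootRefitDeviance <- function(B, k, seed, nRestarts = 2L, maxIter = 15L) {
  n <- ncol(B); tB <- t(B)
  best <- Inf
  for (r in seq_len(nRestarts)) {
    omega <- withSeed(deriveSeed(seed, 17L * r),
                      drawOmega(rep(1 / k, k), n, 1))
    dev0 <- Inf
    for (it in seq_len(maxIter)) {
      mu <- boundedLSAll(tB, omega)
      omega <- simplexLSAll(B, mu)
      R <- B - mu %*% t(omega)
      dev <- sum(R * R)
      if (is.finite(dev0) && dev0 - dev < 1e-6 * (1 + dev0)) break
      dev0 <- dev
    }
    ld <- n * sum(log(pmax(rowSums(R * R) / n, 1e-12)))
    if (ld < best) best <- ld
  }
  best
}

#' Select the number of latent cell types by bootstrapped deviance
#'
#' For each candidate K the model is refitted on bootstrap resamples of
#' the samples (probes fixed, drawn with replacement); each refit yields
#' a profiled-likelihood deviance (per-probe residual variances profiled
#' out). The selected K minimizes the variance of the bootstrapped
#' deviances across resamples (the mean is available as an option); ties
#' go to the smaller K. Too few components leave heterogeneous
#' lack-of-fit that fluctuates with the resample; too many chase
#' resample-specific noise; at the true K the refits are stable, which
#' is what the variance criterion rewards. For speed the selection runs
#' on the \code{nTop} most variable probes, where the cell-type signal
#' concentrates. The full K x bootstrap deviance table is returned for
#' audit.
#'
#' @param betas probes x samples matrix or \linkS4class{MethylationSet}.
#' @param kRange integer candidates within [1, 10].
#' @param nBoot number of bootstrap resamples (>= 2).
#' @param seed integer seed.
#' @param criterion \code{"variance"} (default) or \code{"mean"}.
#' @param nTop number of most-variable probes used.
#' @param nRestarts,maxIter ALS restarts and iteration cap per refit.
#' @return list with \code{k} (selected), \code{devianceTable}
#'   (|kRange| x nBoot) and \code{criterion} values.
#' @export
selectK <- function(betas, kRange = 1:4, nBoot = 16L, seed = 1L,
                    criterion = c("variance", "mean"), nTop = 2000L,
                    nRestarts = 1L, maxIter = 20L) {
  criterion <- match.arg(criterion)
  if (methods::is(betas, "MethylationSet")) betas <- betaValues(betas)
  B <- as.matrix(betas)
  kRange <- sort(unique(as.integer(kRange)))
  if (length(kRange) == 0) stop("kRange must be non-empty")
  if (any(kRange < 1 | kRange > 10)) stop("kRange must lie within [1, 10]")
  if (nBoot < 2) stop("nBoot must be >= 2")
  n <- ncol(B)
  if (nrow(B) > nTop) {
    v <- rowSums((B - rowMeans(B))^2)
    B <- B[order(v, decreasing = TRUE)[seq_len(nTop)], , drop = FALSE]
  }
  bootIdx <- withSeed(deriveSeed(seed, 211L), {
    replicate(nBoot, sample.int(n, n, replace = TRUE))
  })
  dev <- matrix(NA_real_, length(kRange), nBoot,
                dimnames = list(paste0("K", kRange), NULL))
  for (i in seq_along(kRange)) {
    for (b in seq_len(nBoot)) {
      Bb <- B[, bootIdx[, b], drop = FALSE]
      dev[i, b] <- bootRefitDeviance(Bb, kRange[i],
                                     seed = deriveSeed(seed,
                                       1000L * i + b),
                                     nRestarts = nRestarts,
                                     maxIter = maxIter)
    }
  }
  crit <- if (criterion == "variance") apply(dev, 1, var)
          else rowMeans(dev)
  sel <- kRange[which.min(crit)]
  list(k = sel, devianceTable = dev, criterion = crit,
       criterionType = criterion)
}

#' Correlate an inferred proportion column with measured fractions
#'
#' Pearson correlation with a two-sided t-distribution p-value, used to
#' validate inferred cell proportions against an external measurement
#' (e.g. flow-cytometry memory-cell fractions).
#'
#' @param omegaColumn inferred proportions (numeric, length >= 3).
#' @param measuredFractions measured proportions, same length.
#' @return list with \code{r} and \code{p}.
#' @export
validateAgainstReference <- function(omegaColumn, measuredFractions) {
  if (length(omegaColumn) != length(measuredFractions) ||
      length(omegaColumn) < 3)
    stop("vectors must have equal length >= 3")
  if (stats::sd(omegaColumn) == 0 || stats::sd(measuredFractions) == 0)
    stop("correlation undefined: zero variance in input")
  ct <- cor.test(omegaColumn, measuredFractions, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
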