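#' Probe-level quality filtering
#'
#' Removes probes failing any of five rules, applied in this fixed
#' order so the per-rule counts (each counted among probes surviving the
#' earlier rules) are part of the contract:
#' \enumerate{
#'   \item detection p-value above \code{detP} in at least
#'     \code{detPFraction} of samples (default: any sample);
#'   \item bead count below \code{beadCount} (strictly \code{< 3} by
#'     default, so a count of exactly 3 is retained);
#'   \item no CpG at the probed position (\code{hasCpG} flag false);
#'   \item probed CpG near a SNP (\code{nearSNP} flag);
#'   \item probe aligning to multiple locations (\code{multiMap} flag).
#' }
#' X-chromosome probes are retained by default (\code{dropXChr = FALSE});
#' the switch exists for mixed-sex designs.
#'
#' @param x a \linkS4class{MethylationSet} whose rowData carries
#'   \code{minBeadCount}, \code{hasCpG}, \code{nearSNP}, \code{multiMap}
#'   and whose assays include \code{detP} (or rowData \code{maxDetP}).
#' @param detP detection p-value threshold (probe fails when p is
#'   strictly above it).
#' @param detPFraction fraction of samples that must exceed the
#'   threshold for the probe to fail; the default \code{0} means a
#'   single sample suffices.
#' @param beadCount minimum bead count; probes strictly below fail.
#' @param dropXChr drop chrX probes (off by default).
#' @return the filtered MethylationSet; the
#'   \code{FilterReport} (list with \code{counts} data.frame, removed
#'   ids per rule and \code{retained}) is stored in
#'   \code{metadata(x)$filterReport} and readable via
#'   \code{\link{filterReport}}.
#' @export
filterProbes <- function(x, detP = 0.01, detPFraction = 0,
                         beadCount = 3, dropXChr = FALSE) {
  ann <- probeAnno(x)
  need <- c("minBeadCount", "hasCpG", "nearSNP", "multiMap")
  miss <- setdiff(need, colnames(ann))
  if (length(miss) > 0)
    stop("probe annotation lacks required column(s): ",
         paste(miss, collapse = ", "))
  hasDetP <- "detP" %in% SummarizedExperiment::assayNames(x)
  if (!hasDetP && !"maxDetP" %in% colnames(ann))
    stop("probe annotation lacks required column(s): detP assay or maxDetP")

  alive <- rep(TRUE, nrow(x))
  names(alive) <- rownames(x)
  rules <- list()

  failDetP <- if (hasDetP) {
    dp <- SummarizedExperiment::assay(x, "detP")
    frac <- rowMeans(dp > detP)
    if (detPFraction <= 0) frac > 0 else frac >= detPFraction
  } else ann$maxDetP > detP
  rules$detection_p <- failDetP
  rules$bead_count <- ann$minBeadCount < beadCount
  rules$no_cpg <- !ann$hasCpG
  rules$snp_proximity <- ann$nearSNP
  rules$multi_mapping <- ann$multiMap
  if (dropXChr && "chr" %in% colnames(ann))
    rules$x_chromosome <- ann$chr %in% c("chrX", "X")

  removedIds <- list()
  counts <- data.frame(filter = names(rules),
                       removed = NA_integer_,
                       stringsAsFactors = FALSE)
  for (i in seq_along(rules)) {
    hit <- alive & rules[[i]] & !is.na(rules[[i]])
    removedIds[[names(rules)[i]]] <- names(alive)[hit]
    counts$removed[i] <- sum(hit)
    alive <- alive & !hit
  }
  report <- list(counts = counts, removedIds = removedIds,
                 retained = sum(alive), input = nrow(x),
                 order = names(rules))
  out <- x[alive, ]
  S4Vectors::metadata(out)$filterReport <- report
  out
}

#' @rdname filterProbes
#' @export
filterReport <- function(x) S4Vectors::metadata(x)$filterReport

## ---- three-state beta-mixture EM -------------------------------------

## Weighted method-of-moments beta parameter update; floors keep the
## component proper when a state nearly empties.
betaMoments <- function(x, w) {
  sw <- sum(w)
  if (sw < 1e-8) return(c(1, 1))
  m <- sum(w * x) / sw
  v <- sum(w * (x - m)^2) / sw
  m <- min(max(m, 1e-3), 1 - 1e-3)
  v <- max(min(v, m * (1 - m) * 0.99), 1e-6)
  nu <- m * (1 - m) / v - 1
  c(max(m * nu, 0.05), max((1 - m) * nu, 0.05))
}

fitBetaMixture3 <- function(x, tol = 1e-6, maxIter = 500) {
  x <- pmin(pmax(x, 1e-4), 1 - 1e-4)
  z <- cbind(x < 1 / 3, x >= 1 / 3 & x <= 2 / 3, x > 2 / 3) * 1
  pi <- pmax(colMeans(z), 1e-3); pi <- pi / sum(pi)
  par <- sapply(1:3, function(k) betaMoments(x, z[, k]))
  ll0 <- -Inf; converged <- FALSE
  for (it in seq_len(maxIter)) {
    dens <- sapply(1:3, function(k)
      pi[k] * dbeta(x, par[1, k], par[2, k]))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    z <- dens / tot
    ll <- sum(log(tot))
    pi <- pmax(colMeans(z), 1e-4); pi <- pi / sum(pi)
    par <- sapply(1:3, function(k) betaMoments(x, z[, k]))
    if (is.finite(ll0) && abs(ll - ll0) < tol * (1 + abs(ll))) {
      converged <- TRUE; break
    }
    ll0 <- ll
  }
  ## order states by mean so 1=unmethylated, 2=intermediate, 3=methylated
  means <- par[1, ] / colSums(par)
  ord <- order(means)
  list(shape1 = par[1, ord], shape2 = par[2, ord], pi = pi[ord],
       z = z[, ord, drop = FALSE], converged = converged, nIter = it)
}

## Monotone type-II -> type-I map built from two fitted 3-state mixtures:
## quantile-match the U and M states through their beta CDFs and bridge
## the intermediate range linearly.
bmiqMap <- function(fitI, fitII) {
  ## segment boundaries: where the posterior argmax of the type-II
  ## mixture hands over from the U state and to the M state
  grid <- seq(0.001, 0.999, length.out = 999)
  post <- sapply(1:3, function(k)
    fitII$pi[k] * dbeta(grid, fitII$shape1[k], fitII$shape2[k]))
  am <- max.col(post)
  bU <- if (any(am == 1)) max(grid[am == 1]) else grid[1]
  bM <- if (any(am == 3)) min(grid[am == 3]) else grid[length(grid)]
  if (bM <= bU) return(NULL)      # states overlap; caller falls back
  mapU <- function(b) qbeta(pbeta(b, fitII$shape1[1], fitII$shape2[1]),
                            fitI$shape1[1], fitI$shape2[1])
  mapM <- function(b) qbeta(pbeta(b, fitII$shape1[3], fitII$shape2[3]),
                            fitI$shape1[3], fitI$shape2[3])
  fU <- mapU(bU); fM <- mapM(bM)
  if (!is.finite(fU) || !is.finite(fM) || fM <= fU) return(NULL)
  function(b) {
    out <- numeric(length(b))
    lo <- b <= bU; hi <- b >= bM; mid <- !lo & !hi
    out[lo] <- mapU(b[lo])
    out[hi] <- mapM(b[hi])
    out[mid] <- fU + (b[mid] - bU) / (bM - bU) * (fM - fU)
    pmin(pmax(out, 0), 1)
  }
}

#' Beta-mixture quantile normalization of type II probes
#'
#' Fits a three-state (unmethylated / hemimethylated / methylated) beta
#' mixture to the type I and type II probe populations of each sample,
#' then maps the type II distribution onto the type I reference:
#' unmethylated and methylated states are quantile-matched through their
#' fitted beta CDFs and the intermediate range is bridged by monotone
#' linear interpolation. Type I probes are returned unchanged; the map
#' is monotone, so within-sample rank order of type II probes is
#' preserved and output stays in [0, 1]. If the EM fit degenerates or
#' the mixture states overlap, the identity map is used for that sample
#' with a warning.
#'
#' @param x a \linkS4class{MethylationSet} whose rowData carries
#'   \code{designType} ("I"/"II").
#' @param tol,maxIter EM convergence tolerance and iteration cap.
#' @param minProbes minimum probes required per design type.
#' @return the normalized MethylationSet.
#' @export
bmiqNormalize <- function(x, tol = 1e-6, maxIter = 500, minProbes = 100) {
  ann <- probeAnno(x)
  if (!"designType" %in% colnames(ann))
    stop("probe annotation lacks required column(s): designType")
  isII <- ann$designType == "II"
  if (!any(isII)) return(x)
  if (sum(isII) < minProbes || sum(!isII) < minProbes)
    stop("each design type needs >= ", minProbes, " probes")
  beta <- betaValues(x)
  notConverged <- degenerate <- character(0)
  for (j in seq_len(ncol(beta))) {
    fitI <- fitBetaMixture3(beta[!isII, j], tol, maxIter)
    fitII <- fitBetaMixture3(beta[isII, j], tol, maxIter)
    if (!fitI$converged || !fitII$converged)
      notConverged <- c(notConverged, colnames(beta)[j])
    map <- bmiqMap(fitI, fitII)
    if (is.null(map)) {
      degenerate <- c(degenerate, colnames(beta)[j])
      next
    }
    beta[isII, j] <- map(beta[isII, j])
  }
  if (length(notConverged) > 0)
    warning("beta-mixture EM hit the iteration cap for ",
            length(notConverged), " sample(s): ",
            paste(notConverged, collapse = ", "))
  if (length(degenerate) > 0)
    warning("degenerate mixture states; identity map used for: ",
            paste(degenerate, collapse = ", "))
  SummarizedExperiment::assay(x, "beta") <- beta
  S4Vectors::metadata(x)$bmiqLog <- list(notConverged = notConverged,
                                         degenerate = degenerate)
  x
}
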