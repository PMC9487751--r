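#' Build the fixed-effect + cell-proportion design matrix
#'
#' Intercept, group indicators (reference level absorbed) and K-1 of the
#' K inferred cell-proportion columns: simplex rows make the full
#' proportion block collinear with the intercept, so one column (the
#' first by default) is dropped.
#'
#' @param groups character/factor of per-sample group labels.
#' @param omega samples x K proportion matrix (or NULL for no
#'   adjustment).
#' @param dropOmegaCol index of the proportion column to drop.
#' @param refGroup optional reference level for the group factor.
#' @return design matrix with full column rank.
#' @export
buildDesign <- function(groups, omega = NULL, dropOmegaCol = 1L,
                        refGroup = NULL) {
  groups <- factor(groups)
  if (!is.null(refGroup)) groups <- stats::relevel(groups, refGroup)
  X <- model.matrix(~groups)
  colnames(X) <- sub("^groups", "", colnames(X))
  if (!is.null(omega)) {
    omega <- as.matrix(omega)
    if (nrow(omega) != nrow(X))
      stop("omega rows must align with samples")
    adj <- omega[, -dropOmegaCol, drop = FALSE]
    colnames(adj) <- paste0("omega", seq_len(ncol(omega)))[-dropOmegaCol]
    X <- cbind(X, adj)
  }
  if (qr(X)$rank < ncol(X)) {
    q <- qr(X)
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), q$pivot[seq_len(q$rank)])]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "),
         " (did you include the full omega block with an intercept?)")
  }
  X
}

contrastMatrixFor <- function(design, groups, refGroup = NULL) {
  groups <- factor(groups)
  if (!is.null(refGroup)) groups <- stats::relevel(groups, refGroup)
  lev <- levels(groups)
  stopifnot(all(c("NP", "T1", "T2") %in% lev) || length(lev) == 2)
  cn <- colnames(design)
  mk <- function(plus, minus) {
    v <- setNames(numeric(length(cn)), cn)
    if (plus %in% cn) v[plus] <- 1
    if (minus %in% cn) v[minus] <- -1
    v
  }
  if (all(c("NP", "T1", "T2") %in% lev)) {
    ## reference level is NP (alphabetical), so T1/T2 columns are the
    ## differences to NP directly
    cbind(T1_vs_NP = mk("T1", ""), T2_vs_NP = mk("T2", ""),
          T2_vs_T1 = mk("T2", "T1"))
  } else {
    ## two-level design: single contrast second-vs-first level
    nm <- paste0(lev[2], "_vs_", lev[1])
    out <- cbind(mk(lev[2], ""))
    colnames(out) <- nm
    out
  }
}

#' Per-probe linear models on M-values with empirical-Bayes moderation
#'
#' Ordinary least squares per probe on M-values against the supplied
#' design, with residual variances shrunk toward a common prior by
#' empirical-Bayes moderation (limma) and moderated t / two-sided p per
#' contrast. A plain-OLS path (\code{moderated = FALSE}) reports the
#' unmoderated statistics.
#'
#' @param mMatrix probes x samples matrix of M-values.
#' @param design design matrix from \code{\link{buildDesign}}.
#' @param contrasts contrast matrix (columns = contrasts); by default
#'   derived from the group columns found in the design.
#' @param groups per-sample labels (needed for the default contrasts).
#' @param moderated use empirical-Bayes moderation (default TRUE).
#' @param refGroup optional reference level for the default contrasts.
#' @return data.frame with one row per probe x contrast: \code{probe},
#'   \code{contrast}, \code{coef}, \code{t}, \code{p}, \code{df}.
#' @export
fitProbeModels <- function(mMatrix, design, contrasts = NULL,
                           groups = NULL, moderated = TRUE,
                           refGroup = NULL) {
  mMatrix <- as.matrix(mMatrix)
  if (nrow(design) != ncol(mMatrix))
    stop("design rows must align with samples")
  if (nrow(mMatrix) < 1) stop("no probes to fit")
  if (nrow(design) - ncol(design) < 2)
    stop("at least 2 residual degrees of freedom are required")
  if (is.null(contrasts)) {
    if (is.null(groups)) stop("supply either contrasts or groups")
    contrasts <- contrastMatrixFor(design, groups, refGroup)
  }
  fit <- limma::lmFit(mMatrix, design)
  cf <- limma::contrasts.fit(fit, contrasts)
  if (moderated && nrow(mMatrix) >= 2) {
    eb <- limma::eBayes(cf)
    tt <- eb$t; pp <- eb$p.value; df <- eb$df.total
  } else {
    sigma <- cf$sigma
    tt <- cf$coefficients / (cf$stdev.unscaled * sigma)
    df <- cf$df.residual
    pp <- 2 * pt(-abs(tt), df)
    df <- matrix(df, nrow(tt), ncol(tt))
  }
  out <- do.call(rbind, lapply(colnames(contrasts), function(cn) {
    data.frame(probe = rownames(mMatrix), contrast = cn,
               coef = cf$coefficients[, cn], t = tt[, cn], p = pp[, cn],
               df = if (is.matrix(df)) df[, match(cn, colnames(tt))]
                    else df,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p numeric p-values in [0, 1].
#' @return q-values (monotone step-up adjustment).
#' @export
adjustFdr <- function(p) {
  stopIfNot01(p, "p-values")
  p.adjust(p, method = "BH")
}

#' Per-probe group mean beta difference
#'
#' Delta-beta is the difference of group mean beta values
#' (group2 minus group1) on the normalized, unadjusted beta scale.
#'
#' @param betas probes x samples beta matrix or
#'   \linkS4class{MethylationSet}.
#' @param groups per-sample labels.
#' @param contrast length-2 character: \code{c(group1, group2)}; the
#'   result is mean(group2) - mean(group1).
#' @return named numeric vector of delta-beta per probe.
#' @export
computeDeltaBeta <- function(betas, groups, contrast) {
  if (methods::is(betas, "MethylationSet")) betas <- betaValues(betas)
  stopifnot(length(contrast) == 2)
  g1 <- which(groups == contrast[1]); g2 <- which(groups == contrast[2])
  if (length(g1) == 0 || length(g2) == 0)
    stop("empty contrast group: ",
         paste(contrast[c(length(g1) == 0, length(g2) == 0)],
               collapse = ", "))
  rowMeans(betas[, g2, drop = FALSE]) - rowMeans(betas[, g1, drop = FALSE])
}

contrastGroups <- function(contrastLabel) {
  parts <- strsplit(contrastLabel, "_vs_", fixed = TRUE)[[1]]
  c(parts[2], parts[1])    # (reference, test)
}

#' Call differentially methylated probes
#'
#' A probe is a DMP for a contrast iff its BH-adjusted q-value is
#' strictly below \code{qThresh} and |delta-beta| strictly exceeds
#' \code{dbThresh}; direction is the sign of delta-beta. Tightening
#' either threshold can only remove calls.
#'
#' @param stats data.frame from \code{\link{fitProbeModels}} (one
#'   contrast, or pass a subset).
#' @param deltaBeta named vector aligned with \code{stats$probe}.
#' @param qThresh,dbThresh thresholds (defaults 0.05 / 0.05).
#' @return the stats data.frame augmented with \code{q},
#'   \code{deltaBeta}, \code{isDMP}, \code{direction}.
#' @export
callDmps <- function(stats, deltaBeta, qThresh = 0.05, dbThresh = 0.05) {
  if (is.null(names(deltaBeta)))
    stop("deltaBeta must be named by probe id")
  if (!all(stats$probe %in% names(deltaBeta)))
    stop("probe ids in stats and deltaBeta are misaligned")
  out <- stats
  out$q <- ave(out$p, out$contrast, FUN = adjustFdr)
  out$deltaBeta <- unname(deltaBeta[out$probe])
  out$isDMP <- out$q < qThresh & abs(out$deltaBeta) > dbThresh
  out$direction <- ifelse(out$deltaBeta >= 0, "hyper", "hypo")
  out
}

#' DMP table for every contrast of a cohort
#'
#' Convenience wrapper running \code{\link{fitProbeModels}} on M-values,
#' BH adjustment and delta-beta computation per contrast, returning the
#' long DMP table.
#'
#' @param x a \linkS4class{MethylationSet}.
#' @param omega samples x K proportions (NULL = unadjusted model).
#' @param qThresh,dbThresh DMP thresholds.
#' @param moderated empirical-Bayes moderation switch.
#' @param eps clipping constant for the M transform.
#' @param refGroup optional reference group level (e.g. "control").
#' @return long data.frame as \code{\link{callDmps}}.
#' @export
dmpTable <- function(x, omega = NULL, qThresh = 0.05, dbThresh = 0.05,
                     moderated = TRUE, eps = 1e-3, refGroup = NULL) {
  groups <- sampleGroups(x)
  design <- buildDesign(groups, omega, refGroup = refGroup)
  M <- betaToM(betaValues(x), eps)
  stats <- fitProbeModels(M, design, groups = groups,
                          moderated = moderated, refGroup = refGroup)
  beta <- betaValues(x)
  out <- do.call(rbind, lapply(split(stats, stats$contrast), function(s) {
    cg <- contrastGroups(s$contrast[1])
    dbv <- computeDeltaBeta(beta, groups, cg)
    callDmps(s, dbv, qThresh, dbThresh)
  }))
  rownames(out) <- NULL
  out[order(out$contrast, out$q), ]
}

#' Map DMPs to differentially methylated genes
#'
#' Every gene with at least one DMP becomes a DMG. Its direction is the
#' majority direction of its DMPs; ties are broken by the direction of
#' the member DMP with the smallest q-value. Probes annotated to several
#' genes count for each of them; unannotated probes are skipped (and
#' counted in the returned attributes).
#'
#' @param dmps DMP table (\code{\link{callDmps}} output, any number of
#'   contrasts) -- only rows with \code{isDMP} are used.
#' @param annotation probe -> gene map: data.frame with columns
#'   \code{probe}, \code{gene} (e.g. \code{\link{probeGenes}}).
#' @return data.frame with one row per gene x contrast: \code{gene},
#'   \code{contrast}, \code{nHyper}, \code{nHypo}, \code{direction},
#'   \code{representativeProbe}, \code{minQ}.
#' @export
mapDmpsToGenes <- function(dmps, annotation) {
  hits <- dmps[dmps$isDMP, , drop = FALSE]
  merged <- merge(hits, annotation, by = "probe")
  nUnannotated <- length(setdiff(hits$probe, annotation$probe))
  if (nrow(merged) == 0) {
    out <- data.frame(gene = character(0), contrast = character(0),
                      nHyper = integer(0), nHypo = integer(0),
                      direction = character(0),
                      representativeProbe = character(0),
                      minQ = numeric(0))
    attr(out, "nUnannotated") <- nUnannotated
    return(out)
  }
  sp <- split(merged, list(merged$gene, merged$contrast), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    nHyper <- sum(g$direction == "hyper")
    nHypo <- sum(g$direction == "hypo")
    best <- g[which.min(g$q), ]
    dir <- if (nHyper > nHypo) "hyper"
           else if (nHypo > nHyper) "hypo"
           else best$direction
    data.frame(gene = g$gene[1], contrast = g$contrast[1],
               nHyper = nHyper, nHypo = nHypo, direction = dir,
               representativeProbe = best$probe, minQ = best$q,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out <- out[order(out$contrast, out$minQ), ]
  attr(out, "nUnannotated") <- nUnannotated
  out
}

#' Classical multidimensional scaling of samples
#'
#' Classical MDS (double-centred squared Euclidean distances,
#' eigendecomposition) on the \code{nTop} most variable probes;
#' variance explained is eigenvalue over the sum of positive
#' eigenvalues.
#'
#' @param betas beta matrix or \linkS4class{MethylationSet}.
#' @param nTop number of most-variable probes used.
#' @param nComponents number of coordinates returned (truncated with a
#'   warning when it exceeds samples - 1).
#' @return list with \code{coords} (samples x components) and
#'   \code{varExplained}.
#' @export
mdsCoordinates <- function(betas, nTop = 1000L, nComponents = 6L) {
  if (methods::is(betas, "MethylationSet")) betas <- betaValues(betas)
  B <- as.matrix(betas)
  if (ncol(B) < 3) stop("MDS needs at least 3 samples")
  if (nComponents > ncol(B) - 1) {
    warning("nComponents truncated to samples - 1")
    nComponents <- ncol(B) - 1L
  }
  v <- apply(B, 1, var)
  top <- order(v, decreasing = TRUE)[seq_len(min(nTop, nrow(B)))]
  d <- dist(t(B[top, , drop = FALSE]))
  mds <- cmdscale(d, k = nComponents, eig = TRUE)
  pos <- mds$eig[mds$eig > 0]
  list(coords = mds$points,
       varExplained = mds$eig[seq_len(nComponents)] / sum(pos))
}
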