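#' MethylationSet: a CpG beta-value cohort
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding a
#' probes-by-samples beta matrix (assay \code{"beta"}, values in [0,1],
#' optionally an assay \code{"detP"} of per-observation detection
#' p-values), per-sample metadata in \code{colData} (at least
#' \code{group}) and per-probe annotation in \code{rowData} (gene
#' symbols, Infinium design type and the QC flags used by
#' \code{\link{filterProbes}}).
#'
#' @aliases MethylationSet-class
#' @export
setClass("MethylationSet", contains = "SummarizedExperiment")

setValidity("MethylationSet", function(object) {
  msg <- NULL
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "beta values must lie in [0, 1]")
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  if (is.null(msg)) TRUE else msg
})

#' Reference-free mixture decomposition of a beta matrix
#'
#' Result of \code{\link{refFreeDecompose}}: latent cell-type methylomes
#' \code{mu} (probes x K, entries in [0,1]), per-sample mixing proportions
#' \code{omega} (samples x K, rows on the simplex), the residual sum of
#' squares \code{deviance} and the per-iteration deviance trace.
#'
#' @aliases MixtureDecomposition-class
#' @export
setClass("MixtureDecomposition",
  representation(mu = "matrix", omega = "matrix", k = "integer",
                 deviance = "numeric", trace = "numeric",
                 nIter = "integer", converged = "logical",
                 seed = "integer"))

setValidity("MixtureDecomposition", function(object) {
  msg <- NULL
  if (any(object@mu < 0 | object@mu > 1))
    msg <- c(msg, "mu entries must lie in [0, 1]")
  if (any(object@omega < -1e-12))
    msg <- c(msg, "omega entries must be nonnegative")
  if (nrow(object@omega) > 0 &&
      any(abs(rowSums(object@omega) - 1) > 1e-8))
    msg <- c(msg, "omega rows must sum to 1 (tolerance 1e-8)")
  if (ncol(object@mu) != object@k || ncol(object@omega) != object@k)
    msg <- c(msg, "mu/omega column count must equal k")
  if (length(object@trace) > 1 &&
      any(diff(object@trace) > 1e-6 * (1 + object@trace[1])))
    msg <- c(msg, "deviance trace must be non-increasing")
  if (is.null(msg)) TRUE else msg
})

#' Scored protein-protein interaction network
#'
#' Undirected simple graph over gene symbols with a per-edge combined
#' confidence score on the STRING 0-1000 scale; only edges at or above
#' \code{minScore} are retained.
#'
#' @aliases PPINetwork-class
#' @export
setClass("PPINetwork",
  representation(graph = "ANY", minScore = "numeric"))

setValidity("PPINetwork", function(object) {
  g <- object@graph
  msg <- NULL
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (igraph::any_loop(g)) msg <- c(msg, "self-loops are not allowed")
  if (igraph::any_multiple(g)) msg <- c(msg, "multi-edges are not allowed")
  sc <- igraph::E(g)$score
  if (is.null(sc)) msg <- c(msg, "edges must carry a 'score' attribute")
  else if (any(sc < object@minScore))
    msg <- c(msg, "all edge scores must be >= minScore")
  if (is.null(msg)) TRUE else msg
})

#' Result of one module-detection method
#'
#' @aliases ModuleResult-class
#' @export
setClass("ModuleResult",
  representation(method = "character", genes = "character",
                 scores = "numeric", seeds = "character",
                 parameters = "list"))

setValidity("ModuleResult", function(object) {
  ok <- object@method %in% c("mcode", "diamond", "clique_sum",
                             "correlation_clique")
  if (!ok) return("method must be one of mcode/diamond/clique_sum/correlation_clique")
  if (anyDuplicated(object@genes)) return("module genes must be unique")
  TRUE
})

#' Consensus module across module-detection methods
#'
#' Genes returned by at least \code{minMethods} of the supplied methods,
#' with per-gene membership booleans, a flag for seed (DMG) origin and
#' the methylation direction of seed-origin genes.
#'
#' @aliases ConsensusModule-class
#' @export
setClass("ConsensusModule",
  representation(genes = "character", membership = "matrix",
                 minMethods = "integer", seedOrigin = "logical",
                 direction = "character"))

setValidity("ConsensusModule", function(object) {
  msg <- NULL
  if (nrow(object@membership) != length(object@genes))
    msg <- c(msg, "membership rows must match genes")
  if (length(object@genes) > 0 &&
      any(rowSums(object@membership) < object@minMethods))
    msg <- c(msg, "every member must belong to >= minMethods modules")
  if (is.null(msg)) TRUE else msg
})

#' Network co-localization permutation test result
#'
#' @aliases ColocalizationResult-class
#' @export
setClass("ColocalizationResult",
  representation(dObs = "numeric", dNull = "numeric", p = "numeric",
                 nSeeds = "integer", nPerm = "integer"))

setValidity("ColocalizationResult", function(object) {
  msg <- NULL
  if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must lie in (0, 1]")
  if (length(object@dNull) != object@nPerm)
    msg <- c(msg, "null distance count must equal nPerm")
  if (is.null(msg)) TRUE else msg
})

#' Fisher enrichment of a query set in a target set
#'
#' 2x2 contingency counts on a background universe of size N, fold
#' enrichment FE = (a/(a+b)) / ((a+c)/N) and the two-sided Fisher exact
#' p-value; a = query-and-target, b = query only, c = target only,
#' d = neither.
#'
#' @aliases EnrichmentResult-class
#' @export
setClass("EnrichmentResult",
  representation(a = "integer", b = "integer", c = "integer",
                 d = "integer", N = "integer", fe = "numeric",
                 p = "numeric", overlap = "character"))

setValidity("EnrichmentResult", function(object) {
  if (object@a + object@b + object@c + object@d != object@N)
    return("a + b + c + d must equal N")
  if (object@fe < 0) return("fold enrichment must be nonnegative")
  TRUE
})

setMethod("show", "MethylationSet", function(object) {
  cat("MethylationSet:", nrow(object), "probes x", ncol(object), "samples\n")
  grp <- table(SummarizedExperiment::colData(object)$group)
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  fr <- S4Vectors::metadata(object)$filterReport
  if (!is.null(fr)) cat("  filtered:", sum(fr$counts$removed), "probes removed\n")
  invisible(NULL)
})

setMethod("show", "MixtureDecomposition", function(object) {
  cat("MixtureDecomposition: K =", object@k, "|", nrow(object@mu),
      "probes,", nrow(object@omega), "samples\n")
  cat("  deviance", format(object@deviance, digits = 6), "after",
      object@nIter, "iterations;",
      if (object@converged) "converged" else "not converged", "\n")
  invisible(NULL)
})

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork:", igraph::vcount(object@graph), "genes,",
      igraph::ecount(object@graph), "edges (score >=",
      object@minScore, ")\n")
  invisible(NULL)
})

setMethod("show", "ModuleResult", function(object) {
  cat("ModuleResult [", object@method, "]: ", length(object@genes),
      " genes (", sum(object@genes %in% object@seeds), " seeds)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "ConsensusModule", function(object) {
  cat("ConsensusModule:", length(object@genes), "genes in >=",
      object@minMethods, "of", ncol(object@membership), "methods;",
      sum(object@seedOrigin), "of seed (DMG) origin\n")
  invisible(NULL)
})

setMethod("show", "ColocalizationResult", function(object) {
  cat("Colocalization: harmonic distance d_obs =",
      format(object@dObs, digits = 4), "vs null mean",
      format(mean(object@dNull), digits = 4), "| permutation p =",
      format(object@p, digits = 3), "(", object@nPerm, "permutations )\n")
  invisible(NULL)
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("Enrichment: a =", object@a, "b =", object@b, "c =", object@c,
      "d =", object@d, "N =", object@N, "\n  FE =",
      format(object@fe, digits = 4), ", Fisher p =",
      format(object@p, digits = 3), "\n")
  invisible(NULL)
})
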