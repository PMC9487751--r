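## Separation score between retained groups: the DMP count at the
## stated criterion, with the summed evidence (-log10 q over the called
## DMPs) as a continuous secondary component used only to order
## equal-count states.
dmpScore <- function(M, beta, groups, omega, qThresh, dbThresh,
                     refGroup = "control") {
  design <- buildDesign(groups, omega, refGroup = refGroup)
  stats <- fitProbeModels(M, design, groups = groups, refGroup = refGroup)
  cg <- contrastGroups(stats$contrast[1])
  db <- computeDeltaBeta(beta, groups, cg)
  called <- callDmps(stats, db, qThresh, dbThresh)
  c(count = sum(called$isDMP),
    evidence = sum(-log10(pmax(called$q[called$isDMP], 1e-300))))
}

#' Divisive subgroup selection for heterogeneous case/control cohorts
#'
#' Greedy divisive exclusion in the spirit of the diVIsive Shuffling
#' Approach: repeatedly evaluate removal of each currently removable
#' sample (controls only by default, since overlapping controls are the
#' typical contamination), accept the single removal that maximally
#' increases the number of DMPs between the retained groups, and stop
#' when no removal improves the score or the removal budget is reached.
#' Deterministic: candidate ties are broken by sample id.
#'
#' @param x a \linkS4class{MethylationSet} with groups "case"/"control".
#' @param omega samples x K cell proportions (NULL = unadjusted model);
#'   rows are subset alongside samples.
#' @param qThresh,dbThresh the DMP criterion optimized.
#' @param maxRemovedFraction cap on the fraction of removable samples
#'   excluded (default 0.5).
#' @param removable \code{"control"} (default) or \code{"either"}.
#' @param minGroupSize retained groups may not drop below this (3).
#' @param eps M-transform clipping constant.
#' @return list: \code{caseIds}, \code{controlIds} (retained),
#'   \code{removed} (data.frame with step and score), \code{score}
#'   (final DMP count), \code{trace} (score after each accepted step,
#'   starting at the baseline).
#' @export
vistaSubgroups <- function(x, omega = NULL, qThresh = 0.05,
                           dbThresh = 0.05, maxRemovedFraction = 0.5,
                           removable = c("control", "either"),
                           minGroupSize = 3L, eps = 1e-3) {
  removable <- match.arg(removable)
  groups <- sampleGroups(x)
  if (!all(sort(unique(groups)) == c("case", "control")))
    stop("groups must be 'case' and 'control'")
  ids <- colnames(x)
  if (min(table(groups)) < minGroupSize)
    stop("need >= ", minGroupSize, " samples per group")
  beta <- betaValues(x)
  M <- betaToM(beta, eps)
  keep <- rep(TRUE, length(ids)); names(keep) <- ids
  scoreOf <- function(keepVec) {
    om <- if (is.null(omega)) NULL else omega[keepVec, , drop = FALSE]
    dmpScore(M[, keepVec, drop = FALSE], beta[, keepVec, drop = FALSE],
             groups[keepVec], om, qThresh, dbThresh)
  }
  ## lexicographic improvement: a removal is accepted when it raises the
  ## DMP count, or keeps it while strictly raising the summed evidence
  better <- function(a, b) {
    a["count"] > b["count"] ||
      (a["count"] == b["count"] &&
       a["evidence"] > b["evidence"] * (1 + 1e-9))
  }
  cur <- scoreOf(keep)
  trace <- cur["count"]
  removed <- data.frame(sampleId = character(0), step = integer(0),
                        score = integer(0), stringsAsFactors = FALSE)
  pool <- if (removable == "control") ids[groups == "control"] else ids
  budget <- floor(maxRemovedFraction * length(pool))
  step <- 0L
  while (step < budget) {
    cands <- sort(pool[keep[pool]])
    cands <- Filter(function(s) {
      g <- groups[match(s, ids)]
      sum(keep[ids[groups == g]]) - 1 >= minGroupSize
    }, cands)
    if (length(cands) == 0) break
    scores <- vapply(cands, function(s) {
      kv <- keep; kv[s] <- FALSE
      scoreOf(kv)
    }, c(count = 0, evidence = 0))
    best <- 1L
    for (j in seq_along(cands))       # ties: first in sorted id order
      if (better(scores[, j], scores[, best])) best <- j
    if (!better(scores[, best], cur)) break
    step <- step + 1L
    keep[cands[best]] <- FALSE
    cur <- scores[, best]
    trace <- c(trace, cur["count"])
    removed <- rbind(removed,
                     data.frame(sampleId = cands[best], step = step,
                                score = unname(cur["count"]),
                                stringsAsFactors = FALSE))
  }
  list(caseIds = ids[keep & groups == "case"],
       controlIds = ids[keep & groups == "control"],
       removed = removed, score = unname(trace[length(trace)]),
       trace = unname(trace))
}

makeEnrichment <- function(query, target, background, overlapIds = TRUE) {
  query <- unique(query); target <- unique(target)
  background <- unique(background)
  if (length(query) == 0 || length(target) == 0)
    stop("query and target must be non-empty")
  if (!all(query %in% background) || !all(target %in% background))
    stop("query and target must be subsets of the background")
  N <- length(background)
  if (N < 4) stop("background must contain >= 4 elements")
  ov <- intersect(query, target)
  a <- length(ov)
  b <- length(query) - a
  c <- length(target) - a
  d <- N - a - b - c
  fe <- (a / (a + b)) / ((a + c) / N)
  p <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  methods::new("EnrichmentResult", a = as.integer(a), b = as.integer(b),
               c = as.integer(c), d = as.integer(d), N = as.integer(N),
               fe = fe, p = p,
               overlap = if (overlapIds) sort(ov) else character(0))
}

#' Gene-set enrichment by Fisher's exact test
#'
#' 2x2 contingency of query genes vs target (e.g. known disease) genes
#' on a background universe; fold enrichment
#' FE = (a/(a+b)) / ((a+c)/N) and the two-sided Fisher exact p-value.
#'
#' @param queryGenes,targetGenes,backgroundGenes character vectors;
#'   query and target must be subsets of the background (N >= 4).
#' @return an \linkS4class{EnrichmentResult}.
#' @export
genesetEnrichment <- function(queryGenes, targetGenes, backgroundGenes) {
  makeEnrichment(queryGenes, targetGenes, backgroundGenes)
}

#' CpG-set enrichment by Fisher's exact test
#'
#' As \code{\link{genesetEnrichment}} on the CpG universe (e.g. module
#' CpGs vs disease DMPs); the overlap ids are reported for the
#' downstream directionality test.
#'
#' @param moduleCpgs,diseaseDmps,backgroundCpgs character vectors of
#'   probe ids; both sets must be subsets of the background.
#' @return an \linkS4class{EnrichmentResult} with \code{overlap} ids.
#' @export
cpgEnrichment <- function(moduleCpgs, diseaseDmps, backgroundCpgs) {
  makeEnrichment(moduleCpgs, diseaseDmps, backgroundCpgs)
}

#' Effect-direction correlation between two cohorts
#'
#' Pearson (t-based two-sided p) and Spearman correlations of paired
#' per-CpG effects (e.g. pregnancy delta-beta vs disease delta-beta on
#' the overlapping CpGs); the sign of the correlation is the
#' directionality verdict.
#'
#' @param moduleEffects named numeric effects (e.g. delta-beta) in the
#'   first cohort.
#' @param diseaseEffects named numeric effects in the second cohort.
#' @param overlapIds CpG ids present in both (>= 3).
#' @return list: \code{n}, \code{pearsonR}, \code{pearsonP},
#'   \code{spearmanRho}, \code{spearmanP}, \code{sign}.
#' @export
directionCorrelation <- function(moduleEffects, diseaseEffects,
                                 overlapIds = NULL) {
  if (is.null(overlapIds))
    overlapIds <- intersect(names(moduleEffects), names(diseaseEffects))
  overlapIds <- intersect(intersect(overlapIds, names(moduleEffects)),
                          names(diseaseEffects))
  if (length(overlapIds) < 3)
    stop("need >= 3 overlapping CpGs with effects in both cohorts")
  a <- unname(moduleEffects[overlapIds])
  b <- unname(diseaseEffects[overlapIds])
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: zero variance in effects")
  pe <- cor.test(a, b, method = "pearson")
  sp <- suppressWarnings(cor.test(a, b, method = "spearman"))
  list(n = length(overlapIds),
       pearsonR = unname(pe$estimate), pearsonP = pe$p.value,
       spearmanRho = unname(sp$estimate), spearmanP = sp$p.value,
       sign = if (pe$estimate >= 0) "+" else "-")
}
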