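#' Construct a MethylationSet
#'
#' @param beta probes x samples matrix of beta values in [0,1]; rownames
#'   are probe ids, colnames sample ids.
#' @param sampleInfo data.frame with one row per sample; must contain a
#'   \code{group} column (factor or character).
#' @param probeInfo data.frame with one row per probe (gene symbols, QC
#'   flags, design type); may be missing columns that downstream steps
#'   then refuse to use.
#' @param detP optional probes x samples matrix of detection p-values.
#' @return a \linkS4class{MethylationSet}.
#' @export
MethylationSet <- function(beta, sampleInfo, probeInfo = NULL, detP = NULL) {
  beta <- as.matrix(beta)
  stopIfNot01(beta, "beta")
  if (is.null(rownames(beta)))
    rownames(beta) <- sprintf("cg%07d", seq_len(nrow(beta)))
  if (is.null(colnames(beta)))
    colnames(beta) <- sprintf("S%03d", seq_len(ncol(beta)))
  assays <- list(beta = beta)
  if (!is.null(detP)) {
    detP <- as.matrix(detP)
    stopifnot(all(dim(detP) == dim(beta)))
    dimnames(detP) <- dimnames(beta)
    assays$detP <- detP
  }
  if (is.null(probeInfo))
    probeInfo <- data.frame(row.names = rownames(beta))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(sampleInfo, row.names = colnames(beta)),
    rowData = S4Vectors::DataFrame(probeInfo, row.names = rownames(beta)))
  methods::new("MethylationSet", se)
}

#' Accessors for MethylationSet
#'
#' \code{betaValues} returns the beta assay; \code{sampleGroups} the
#' per-sample group labels; \code{probeAnno} the probe annotation as a
#' plain data.frame; \code{probeGenes} a probe -> gene symbol long table
#' (one row per probe/gene pair, comma-separated symbols split).
#'
#' @param x a \linkS4class{MethylationSet}.
#' @return see description.
#' @export
betaValues <- function(x) SummarizedExperiment::assay(x, "beta")

#' @rdname betaValues
#' @export
sampleGroups <- function(x) {
  as.character(SummarizedExperiment::colData(x)$group)
}

#' @rdname betaValues
#' @export
probeAnno <- function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
}

#' @rdname betaValues
#' @export
probeGenes <- function(x) {
  ann <- probeAnno(x)
  if (!"gene" %in% colnames(ann))
    stop("probe annotation lacks a 'gene' column")
  genes <- strsplit(as.character(ann$gene), ";", fixed = TRUE)
  n <- lengths(genes)
  out <- data.frame(probe = rep(rownames(ann), n),
                    gene = unlist(genes, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out[nzchar(out$gene) & !is.na(out$gene), , drop = FALSE]
}

#' Subset samples of a MethylationSet by a predicate on the sample sheet
#'
#' Utility used e.g. to express "female samples only" as a sample-sheet
#' predicate before differential analysis.
#'
#' @param x a \linkS4class{MethylationSet}.
#' @param predicate an expression evaluated in the colData (e.g.
#'   \code{sex == "F"}).
#' @return the subsetted MethylationSet.
#' @export
filterSamples <- function(x, predicate) {
  keep <- eval(substitute(predicate),
               as.data.frame(SummarizedExperiment::colData(x)),
               parent.frame())
  if (!is.logical(keep) || length(keep) != ncol(x))
    stop("predicate must evaluate to one logical per sample")
  x[, which(keep)]
}
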