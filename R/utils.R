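#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames colData
#'   rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats rbeta rgamma runif rnorm var sd cor cor.test
#'   p.adjust phyper dhyper fisher.test cmdscale dist model.matrix
#'   quantile median pt pbeta qbeta dbeta setNames aggregate
#' @importFrom utils head read.delim write.table read.csv write.csv
NULL

## Deterministic seed splitting: every stochastic helper takes a scalar
## seed; children are derived with deriveSeed(master, offset) so that one
## master seed reproduces a whole run while stages stay independent.
deriveSeed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 7919 + 104729 * offset) %% 2147483587)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

clip01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

logit2 <- function(p) log2(p / (1 - p))
ilogit2 <- function(m) 2^m / (1 + 2^m)

#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)) after clipping beta to [eps, 1 - eps] so the
#' transform is defined at the boundaries. \code{mToBeta} is its exact
#' inverse on the clipped range.
#'
#' @param beta numeric vector or matrix of methylation fractions in [0,1].
#' @param eps boundary clipping constant (default 1e-3).
#' @return numeric object of the same shape on the M-value scale.
#' @examples
#' betaToM(0.5)  # 0
#' betaToM(0.8)  # 2
#' @export
betaToM <- function(beta, eps = 1e-3) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  logit2(clip01(beta, eps))
}

#' @rdname betaToM
#' @param M numeric vector or matrix of M-values.
#' @export
mToBeta <- function(M) ilogit2(M)

stopIfNot01 <- function(x, what) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop(what, " must lie in [0, 1]")
  invisible(TRUE)
}
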