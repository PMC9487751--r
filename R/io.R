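#' Writers for the pipeline's tabular artifacts
#'
#' Plain-text exports: beta matrix TSV (probe id index column, sample
#' columns), sample sheet CSV, probe annotation TSV, STRING-dialect edge
#' TSV, GMT gene sets, SIF network export and JSON ground truth.
#'
#' @param x object to write (see each function).
#' @param path output file path.
#' @return the path, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
writeBetaTsv <- function(x, path) {
  b <- if (methods::is(x, "MethylationSet")) betaValues(x) else as.matrix(x)
  df <- data.frame(probe = rownames(b), b, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeSampleSheet <- function(x, path) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeProbeAnnotation <- function(x, path) {
  df <- data.frame(probe = rownames(x), probeAnno(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeStringEdges <- function(x, path) {
  g <- if (methods::is(x, "PPINetwork")) x@graph else x
  e <- igraph::ends(g, igraph::E(g), names = TRUE)
  df <- data.frame(protein1 = e[, 1], protein2 = e[, 2],
                   combined_score = igraph::E(g)$score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeSif <- function(x, path) {
  g <- if (methods::is(x, "PPINetwork")) x@graph else x
  e <- igraph::ends(g, igraph::E(g), names = TRUE)
  writeLines(paste(e[, 1], "pp", e[, 2], sep = "\t"), path)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then member genes,
#' tab-separated.
#'
#' @param sets named list of character vectors (write) / path (read).
#' @param path file path.
#' @param descriptions optional per-set description strings.
#' @return \code{readGmt}: named list of character vectors.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGmt
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0)
    stop("malformed GMT line(s): ", paste(bad, collapse = ", "))
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, "", 1))
}

#' @rdname writers
#' @param truth a ground-truth list from the simulators.
#' @export
writeGroundTruth <- function(truth, path) {
  ser <- lapply(truth, function(el) {
    if (is.matrix(el)) as.data.frame(el) else el
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a beta matrix TSV written by \code{writeBetaTsv}
#' @param path file path.
#' @return numeric matrix with probe rownames.
#' @export
readBetaTsv <- function(path) {
  if (!file.exists(path)) stop("beta matrix file not found: ", path)
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
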