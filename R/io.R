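## Shared file I/O: all tables are TSV with fixed headers; loci travel
## as BED6 (0-based half-open, converted by rtracklayer); gene sets as
## GMT; ground truth and reports as JSON.

.writeTsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path, required = NULL, what = path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!is.null(required)) .needCols(df, required, what)
  df
}

#' Read / write the six-group count table
#'
#' TSV with a \code{mirna} column and the six group columns.
#'
#' @param path File path.
#' @param x A \code{\linkS4class{MirCountSet}}.
#' @return \code{readCounts}: a \code{MirCountSet}; \code{writeCounts}:
#'   the path, invisibly.
#' @export
readCounts <- function(path) {
  df <- .readTsv(path, c("mirna", groupLabels()), "count table")
  m <- as.matrix(df[, groupLabels()])
  rownames(m) <- df$mirna
  MirCountSet(m)
}

#' @rdname readCounts
#' @export
writeCounts <- function(x, path) {
  cnt <- assay(x, "counts")
  .writeTsv(data.frame(mirna = rownames(cnt), cnt, check.names = FALSE),
            path)
}

#' Read / write miRNA loci as BED6
#'
#' @param path BED file path.
#' @param loci Named \code{GRanges}.
#' @return \code{readLoci}: named \code{GRanges}.
#' @export
readLoci <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  names(gr) <- gr$name
  gr
}

#' @rdname readLoci
#' @export
writeLoci <- function(loci, path) {
  loci$name <- names(loci)
  loci$score <- 0L
  rtracklayer::export(loci, path, format = "BED")
  invisible(path)
}

#' Read the score and status tables
#'
#' \code{readTargets}: miRNA target-prediction scores (mirna, gene,
#' context_score, target_score).  \code{readTfBind}: TF binding-scan
#' scores (tf, target, target_class, matrix_score, core_score).
#' \code{readStatus}: gene/TF direction table (name, class, direction,
#' is_tf).  \code{readCt}: Ct table (mirna, group, ct, ct_ref).
#'
#' @param path File path.
#' @return data.frame with the named columns.
#' @export
readTargets <- function(path)
  .readTsv(path, c("mirna", "gene", "context_score", "target_score"),
           "target table")

#' @rdname readTargets
#' @export
readTfBind <- function(path)
  .readTsv(path, c("tf", "target", "target_class", "matrix_score",
                   "core_score"), "TF scan table")

#' @rdname readTargets
#' @export
readStatus <- function(path)
  .readTsv(path, c("name", "class", "direction", "is_tf"),
           "status table")

#' @rdname readTargets
#' @export
readCt <- function(path)
  .readTsv(path, c("mirna", "group", "ct", "ct_ref"), "Ct table")

#' Write every simulated input to a directory
#'
#' Emits counts.tsv, loci.bed, targets.tsv, tfbind.tsv, status.tsv,
#' pathways.gmt, ct.tsv and truth.json.
#'
#' @param sim \code{\link{simulateAll}} output.
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeCounts(sim$counts, p("counts.tsv"))
  writeLoci(sim$loci, p("loci.bed"))
  .writeTsv(sim$targets, p("targets.tsv"))
  .writeTsv(sim$tfbind, p("tfbind.tsv"))
  .writeTsv(sim$status, p("status.tsv"))
  writeGmt(sim$pathways, p("pathways.gmt"))
  .writeTsv(sim$ct, p("ct.tsv"))
  tr <- sim$truth
  jsonlite::write_json(
    list(true_demirs = tr@trueDemirs, true_patterns = tr@truePatterns,
         true_ffls = tr@trueFfls, in_region_mirnas = tr@inRegionMirnas),
    p("truth.json"), dataframe = "rows", auto_unbox = TRUE)
  invisible(stats::setNames(
    p(c("counts.tsv", "loci.bed", "targets.tsv", "tfbind.tsv",
        "status.tsv", "pathways.gmt", "ct.tsv", "truth.json")),
    c("counts", "loci", "targets", "tfbind", "status", "pathways",
      "ct", "truth")))
}

#' Read a truth.json back into a GroundTruth
#'
#' @param path Path to truth.json.
#' @return A \code{\linkS4class{GroundTruth}}.
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  asDf <- function(d, cols) {
    if (is.null(d) || !length(d))
      return(stats::setNames(
        data.frame(matrix(character(), 0, length(cols)),
                   stringsAsFactors = FALSE), cols))
    as.data.frame(d, stringsAsFactors = FALSE)
  }
  new("GroundTruth",
      trueDemirs = asDf(x$true_demirs, c("mirna", "contrast", "direction")),
      truePatterns = asDf(x$true_patterns, c("mirna", "sex", "subtype")),
      trueFfls = asDf(x$true_ffls, c("tf", "mirna", "gene", "ffl_type")),
      inRegionMirnas = as.character(unlist(x$in_region_mirnas)))
}
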