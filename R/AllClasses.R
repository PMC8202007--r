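#' @import methods
#' @useDynLib mirFFL, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom GenomicRanges GRanges seqnames start end width strand strand<- granges
#' @importFrom IRanges IRanges
NULL

## The six pooled libraries of the design: sex (M/F) x tissue
## (W = wild-type normal liver, P = peri-tumor precancerous, T = tumor).
.GROUPS <- c("MW", "MP", "MT", "FW", "FP", "FT")
.TISSUES <- c("W", "P", "T")
.SEXES <- c("M", "F")

#' Group labels of the six-library design
#'
#' The pipeline operates on one pooled sequencing library per group:
#' \code{MW, MP, MT, FW, FP, FT}, i.e. sex (M/F) crossed with tissue
#' (W = wild-type normal liver, P = peri-tumor precancerous tissue,
#' T = hepatic tumor).
#'
#' @return Character vector of the six group labels.
#' @export
#' @examples
#' groupLabels()
groupLabels <- function() .GROUPS

#' Within- and between-sex contrasts
#'
#' The three within-sex contrasts per sex (\code{T/P}, \code{T/W},
#' \code{P/W}, prefixed with the sex) drive the vertical comparison;
#' the three between-sex contrasts (\code{MW/FW}, \code{MP/FP},
#' \code{MT/FT}) drive the horizontal comparison.
#'
#' @param sex One of \code{"M"}, \code{"F"} or \code{"both"}.
#' @return Character vector of contrast labels, \code{"numerator/denominator"}.
#' @export
#' @examples
#' withinSexContrasts("M")
#' betweenSexContrasts()
withinSexContrasts <- function(sex = c("both", "M", "F")) {
  sex <- match.arg(sex)
  one <- function(s) paste0(s, c("T/", "T/", "P/"), s, c("P", "W", "W"))
  switch(sex, M = one("M"), F = one("F"), both = c(one("M"), one("F")))
}

#' @rdname withinSexContrasts
#' @export
betweenSexContrasts <- function() paste0("M", .TISSUES, "/F", .TISSUES)

## ---------------------------------------------------------------------------
## MirCountSet
## ---------------------------------------------------------------------------

#' Container for the six-group miRNA count table
#'
#' \code{MirCountSet} extends \linkS4class{SummarizedExperiment} with a
#' validity contract for the pooled no-replicate design: exactly the six
#' group columns \code{MW, MP, MT, FW, FP, FT} (in that order), integer
#' non-negative counts, and unique miRNA identifiers as rownames.
#' \code{colData} carries the \code{sex} and \code{tissue} factors.
#'
#' @param counts Integer matrix, miRNAs x 6 groups, with rownames (miRNA
#'   ids) and colnames drawn from \code{groupLabels()}.
#' @return A \code{MirCountSet}.
#' @export
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 2,
#'             dimnames = list(c("miR-a", "miR-b"), groupLabels()))
#' MirCountSet(m)
setClass("MirCountSet", contains = "SummarizedExperiment")

setValidity("MirCountSet", function(object) {
  cnt <- assay(object, "counts")
  msg <- character()
  if (!identical(colnames(cnt), .GROUPS))
    msg <- c(msg, sprintf("columns must be exactly %s in order",
                          paste(.GROUPS, collapse = ", ")))
  if (is.null(rownames(cnt)) || anyDuplicated(rownames(cnt)))
    msg <- c(msg, "miRNA ids (rownames) must be present and unique")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' @rdname MirCountSet-class
#' @aliases MirCountSet
#' @export
MirCountSet <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.null(colnames(counts)) && all(.GROUPS %in% colnames(counts)))
    counts <- counts[, .GROUPS, drop = FALSE]
  storage.mode(counts) <- "integer"
  cd <- DataFrame(sex = factor(substr(.GROUPS, 1, 1), levels = .SEXES),
                  tissue = factor(substr(.GROUPS, 2, 2), levels = .TISSUES),
                  row.names = .GROUPS)
  new("MirCountSet",
      SummarizedExperiment(assays = list(counts = counts), colData = cd))
}

setMethod("show", "MirCountSet", function(object) {
  cat("MirCountSet with", nrow(object), "miRNAs across the",
      ncol(object), "pooled libraries\n")
  cat("library totals:",
      paste(colnames(object), colSums(assay(object, "counts")),
            sep = "=", collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic-data generator
#'
#' Holds every knob of the generator that emulates the study design: the
#' number of miRNAs/genes/TFs, per-group sequencing depths, the log-normal
#' baseline abundance distribution, the negative-binomial dispersion
#' \eqn{\phi} (variance \eqn{\mu + \phi\mu^2}), the planted expression
#' patterns per sex, the fold-change multiplier applied per planted grade
#' step, the genomic region and the fraction of miRNA loci placed inside
#' it, the number of planted feed-forward loops per type, and the seed.
#'
#' Defaults describe the emulated study: six pooled libraries of 1e7
#' mapped miRNA reads each, 300 miRNAs with 40 planted patterns per sex
#' in proportions echoing the observed category sizes, \eqn{\phi=0.05},
#' eight-fold planted effects.
#'
#' @param nMirna,nGene,nTf Entity counts.
#' @param librarySizes Named numeric of length 6 (reads per group).
#' @param baselineLogMean,baselineLogSd Log-normal parameters of baseline
#'   relative abundance (arbitrary units; normalised internally).
#' @param dispersion NB dispersion \eqn{\phi \ge 0}; 0 gives Poisson.
#' @param plantedPatterns Planted expression patterns: a named numeric
#'   vector (subtype label -> count, planted on the same miRNAs in both
#'   sexes, i.e. fully shared) or a list with any of \code{shared}
#'   (same miRNAs, both sexes), \code{M} and \code{F} (sex-unique
#'   disjoint blocks).  Sex-unique patterns create true between-sex
#'   differences in the tissues they perturb.
#' @param effectFold Fold multiplier per grade step for planted miRNAs
#'   (\eqn{\ge 1}).
#' @param region \code{GRanges} of length 1, the imprinted-region interval.
#' @param fracInRegion Fraction of miRNA loci placed inside \code{region}.
#' @param nPlantedFfl Named numeric: planted loops per type
#'   (\code{TF-FFL}, \code{miRNA-FFL}, \code{composite-FFL}).
#' @param nDecoy Number of decoy (threshold-failing) score rows.
#' @param noisePassing If \code{TRUE}, also add threshold-passing noise
#'   edges that close no new triangle.
#' @param seed Integer seed; every draw of the generator is derived from it.
#' @return A \code{SimConfig} object.
#' @export
#' @examples
#' cfg <- simConfig(nMirna = 50, seed = 1)
#' cfg
setClass("SimConfig", representation(
  nMirna = "integer", nGene = "integer", nTf = "integer",
  librarySizes = "numeric",
  baselineLogMean = "numeric", baselineLogSd = "numeric",
  dispersion = "numeric",
  plantedPatterns = "list",
  effectFold = "numeric",
  region = "GRanges",
  fracInRegion = "numeric",
  nPlantedFfl = "numeric",
  nDecoy = "integer",
  noisePassing = "logical",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nMirna < 1L) msg <- c(msg, "nMirna must be >= 1")
  if (any(object@librarySizes <= 0))
    msg <- c(msg, "library sizes must be positive")
  if (length(object@librarySizes) != 6L)
    msg <- c(msg, "librarySizes must have length 6")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@effectFold < 1) msg <- c(msg, "effectFold must be >= 1")
  if (object@fracInRegion < 0 || object@fracInRegion > 1)
    msg <- c(msg, "fracInRegion must lie in [0, 1]")
  if (any(object@nPlantedFfl < 0)) msg <- c(msg, "nPlantedFfl must be >= 0")
  bad <- setdiff(unlist(lapply(object@plantedPatterns, names)),
                 names(.SUBTYPE_GRADES))
  bad <- setdiff(bad, c("flat"))
  if (length(bad))
    msg <- c(msg, paste("unknown subtype label(s):", paste(bad, collapse = ", ")))
  if (sum(unlist(object@plantedPatterns)) > object@nMirna)
    msg <- c(msg, "more planted patterns than miRNAs")
  if (length(msg)) msg else TRUE
})

#' Default Dlk1-Dio3 region placeholder
#'
#' The mouse Dlk1-Dio3 imprinted cluster sits on chromosome 12qF1; the
#' exact interval is a configuration value.  This default is a documented
#' placeholder interval on chr12 used by the simulator and the pipeline
#' when no region is supplied.
#'
#' @return A length-1 \code{GRanges}.
#' @export
#' @examples
#' dlk1Dio3Region()
dlk1Dio3Region <- function() {
  gr <- GRanges("chr12", IRanges(start = 109540001, end = 110000000))
  names(gr) <- "Dlk1-Dio3 GIR, chr12qF1"
  gr
}

#' @rdname SimConfig-class
#' @aliases simConfig SimConfig
#' @export
simConfig <- function(nMirna = 300L, nGene = 400L, nTf = 30L,
                      librarySizes = stats::setNames(rep(1e7, 6), .GROUPS),
                      baselineLogMean = 6, baselineLogSd = 1.5,
                      dispersion = 0.05,
                      plantedPatterns = list(
                        shared = c(a1 = 12, a2 = 4, a3 = 4, b1 = 4,
                                   b2 = 3, c1 = 5, c2 = 3, d1 = 3,
                                   d2 = 2),
                        M = c(a1 = 3, c1 = 2),
                        F = c(a1 = 5, b2 = 3, c1 = 2)),
                      effectFold = 8,
                      region = dlk1Dio3Region(),
                      fracInRegion = 0.5,
                      nPlantedFfl = c("TF-FFL" = 8, "miRNA-FFL" = 4,
                                      "composite-FFL" = 4),
                      nDecoy = 200L, noisePassing = FALSE, seed = 1L) {
  ## canonical form: list(shared=, M=, F=); a bare vector is fully
  ## shared, and identical M/F vectors (legacy form) collapse to shared
  none <- stats::setNames(numeric(), character())
  if (!is.list(plantedPatterns)) {
    plantedPatterns <- list(shared = plantedPatterns, M = none, F = none)
  } else {
    pp <- plantedPatterns
    if (is.null(pp$shared) && identical(pp$M, pp$F) && !is.null(pp$M))
      pp <- list(shared = pp$M)
    plantedPatterns <- list(shared = pp$shared %||% none,
                            M = pp$M %||% none, F = pp$F %||% none)
  }
  if (is.null(names(librarySizes))) names(librarySizes) <- .GROUPS
  new("SimConfig",
      nMirna = as.integer(nMirna), nGene = as.integer(nGene),
      nTf = as.integer(nTf), librarySizes = librarySizes[.GROUPS],
      baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
      dispersion = dispersion,
      plantedPatterns = plantedPatterns[c("shared", "M", "F")],
      effectFold = effectFold, region = region,
      fracInRegion = fracInRegion, nPlantedFfl = nPlantedFfl,
      nDecoy = as.integer(nDecoy), noisePassing = noisePassing,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nMirna, "miRNAs,", object@nGene, "genes,",
      object@nTf, "TFs; phi =", object@dispersion,
      "; effect fold =", object@effectFold, "; seed =", object@seed, "\n")
  cat("  planted patterns (shared/M/F):",
      paste(vapply(object@plantedPatterns, sum, 0), collapse = "/"),
      "; planted FFLs:", sum(object@nPlantedFfl), "\n")
})

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Planted ground truth of a simulation
#'
#' Records the answer key of a synthetic run: the truly differential
#' (miRNA, contrast, direction) triples, the planted per-sex subtype of
#' each patterned miRNA, the planted feed-forward loops, and the miRNAs
#' whose locus falls inside the configured genomic region.
#'
#' @slot trueDemirs data.frame(mirna, contrast, direction).
#' @slot truePatterns data.frame(mirna, sex, subtype).
#' @slot trueFfls data.frame(tf, mirna, gene, ffl_type).
#' @slot inRegionMirnas character vector of miRNA ids.
#' @export
setClass("GroundTruth", representation(
  trueDemirs = "data.frame", truePatterns = "data.frame",
  trueFfls = "data.frame", inRegionMirnas = "character"))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@trueDemirs), "planted DEMIR calls,",
      nrow(object@truePatterns), "planted patterns,",
      nrow(object@trueFfls), "planted FFLs,",
      length(object@inRegionMirnas), "in-region miRNAs\n")
})

#' Accessors for GroundTruth
#'
#' @param x A \code{GroundTruth}.
#' @return The corresponding slot: a data.frame (or character vector for
#'   \code{inRegionMirnas}).
#' @name GroundTruth-accessors
#' @export
trueDemirs <- function(x) x@trueDemirs
#' @rdname GroundTruth-accessors
#' @export
truePatterns <- function(x) x@truePatterns
#' @rdname GroundTruth-accessors
#' @export
trueFfls <- function(x) x@trueFfls
#' @rdname GroundTruth-accessors
#' @export
inRegionMirnas <- function(x) x@inRegionMirnas

## ---------------------------------------------------------------------------
## SubNetwork
## ---------------------------------------------------------------------------

#' Feed-forward-loop sub-network
#'
#' A sub-network groups the edges of all feed-forward loops of one type
#' (TF-, miRNA-, or composite-FFL), or the hub-induced secondary TF
#' sub-network.  Nodes are typed (gene/miRNA/TF) and carry their degree
#' within the sub-network (undirected incident edge count).
#'
#' @slot name One of \code{TF-SNW}, \code{miRNA-SNW}, \code{composite-SNW},
#'   \code{secondary TF-SNW}.
#' @slot nodes data.frame(node, class, degree).
#' @slot edges data.frame(source, target, relation).
#' @slot fflCount Number of FFLs the sub-network was built from.
#' @export
setClass("SubNetwork", representation(
  name = "character", nodes = "data.frame", edges = "data.frame",
  fflCount = "integer"))

setValidity("SubNetwork", function(object) {
  msg <- character()
  if (nrow(object@edges)) {
    deg <- table(c(object@edges$source, object@edges$target))
    got <- object@nodes$degree[match(names(deg), object@nodes$node)]
    if (any(is.na(got)) || any(got != as.integer(deg)))
      msg <- c(msg, "node degrees must equal incident edge counts")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SubNetwork", function(object) {
  cat(object@name, ":", nrow(object@nodes), "nodes (",
      paste(names(table(object@nodes$class)), table(object@nodes$class),
            sep = "=", collapse = ", "),
      "),", nrow(object@edges), "edges,", object@fflCount, "FFLs\n")
})

#' Accessors for SubNetwork
#'
#' @param x A \code{SubNetwork}.
#' @return \code{snwNodes}/\code{snwEdges}: data.frame; \code{fflCount}:
#'   integer; \code{snwName}: character.
#' @name SubNetwork-accessors
#' @export
snwNodes <- function(x) x@nodes
#' @rdname SubNetwork-accessors
#' @export
snwEdges <- function(x) x@edges
#' @rdname SubNetwork-accessors
#' @export
fflCount <- function(x) x@fflCount
#' @rdname SubNetwork-accessors
#' @export
snwName <- function(x) x@name
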