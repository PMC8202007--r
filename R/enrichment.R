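## Hypergeometric over-representation of predicted target genes in
## pathway gene sets, reported in the Count / % / Log10(P) / Log10(q)
## convention.

#' Over-representation analysis of a gene set
#'
#' Upper-tail hypergeometric test of the overlap between \code{query}
#' and each term: \eqn{p = P(X \ge count)} with \eqn{X} hypergeometric
#' on (term size, universe size - term size, query size), terms first
#' intersected with the universe.  Benjamini-Hochberg q-values are
#' computed across the reported terms; results are sorted by p.
#'
#' @param query Character vector of genes (must be within
#'   \code{universe}).
#' @param universe Character vector, the background gene set.
#' @param terms Named list of character vectors (e.g. from
#'   \code{\link{readGmt}}).
#' @param minOverlap Minimum overlap for a term to be reported
#'   (default 3).
#' @return data.frame(term, count, percent, log10_p, log10_q, p, q),
#'   sorted by p ascending.
#' @export
#' @examples
#' uni <- paste0("g", 1:50)
#' ora(paste0("g", 1:10), uni,
#'     list(A = paste0("g", 1:8), B = paste0("g", 40:50)), minOverlap = 1)
ora <- function(query, universe, terms, minOverlap = 3L) {
  query <- unique(query); universe <- unique(universe)
  if (!length(query) || !length(universe))
    stop("empty query or universe")
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  rows <- lapply(names(terms), function(nm) {
    term <- intersect(unique(terms[[nm]]), universe)
    cnt <- length(intersect(query, term))
    if (cnt < minOverlap) return(NULL)
    p <- stats::phyper(cnt - 1, length(term),
                       length(universe) - length(term), length(query),
                       lower.tail = FALSE)
    data.frame(term = nm, count = cnt,
               percent = round(100 * cnt / length(query), 2),
               p = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(term = character(), count = integer(),
                      percent = numeric(), log10_p = numeric(),
                      log10_q = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows$log10_p <- log10(rows$p)
  rows$log10_q <- log10(rows$q)
  rows <- rows[order(rows$p), c("term", "count", "percent",
                                "log10_p", "log10_q", "p", "q")]
  rownames(rows) <- NULL
  rows
}

#' Target gene set of in-region miRNAs
#'
#' The union of predicted targets of the in-region DEMIRs, intersected
#' with the supplied down-regulated gene set — the query set for the
#' pathway over-representation stage.
#'
#' @param regionMirnas Character vector of in-region miRNA ids.
#' @param mirnaEdges miRNA-target edge data.frame
#'   (\code{\link{buildMirnaTargets}} output).
#' @param downGenes Character vector of down-regulated genes.
#' @return Character vector of query genes.
#' @export
targetsOfRegionMirnas <- function(regionMirnas, mirnaEdges, downGenes) {
  hit <- mirnaEdges$relation == "miRNA-gene" &
    mirnaEdges$source %in% regionMirnas
  sort(intersect(unique(mirnaEdges$target[hit]), downGenes))
}

#' Read gene sets in GMT format
#'
#' Thin wrapper around \code{fgsea::gmtPathways}.
#'
#' @param path Path to a .gmt file.
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) fgsea::gmtPathways(path)

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Second-column description (recycled).
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
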