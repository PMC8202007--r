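## Localization of differential miRNAs to a genomic imprinted region
## (the horizontal, between-sex comparison).

#' Count DEMIRs inside a genomic region, per contrast and pooled
#'
#' For each contrast, splits its DEMIRs into inside / outside the region
#' (and unplaced, for miRNAs with no locus — counted, never dropped) and
#' reports the in-region fraction as a percentage at one decimal, plus
#' the up/down x in/out split.  A pooled row aggregates the union of all
#' contrasts' DEMIRs.  Membership uses the locus midpoint by default, so
#' no miRNA is double-assigned; \code{mode = "overlap"} uses any overlap
#' instead.
#'
#' @param records Significant differential-expression records
#'   (data.frame with \code{mirna}, \code{contrast}, \code{direction}),
#'   e.g. \code{callDemirs(...)$records}.
#' @param loci \code{GRanges} of miRNA loci, names = miRNA ids.
#' @param region Length-1 \code{GRanges}.
#' @param mode \code{"midpoint"} (default) or \code{"overlap"}.
#' @return list(perContrast = data.frame(contrast, inside, outside,
#'   unplaced, total, pct, up_in, up_out, down_in, down_out), pooled =
#'   one-row data.frame of the union, unplaced = character vector of
#'   unplaced miRNA ids).
#' @export
locateInRegion <- function(records, loci, region,
                           mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(length(region) == 1L, !is.null(names(loci)))
  .needCols(records, c("mirna", "contrast", "direction"), "records")
  insideOf <- function(gr) {
    if (mode == "midpoint") {
      m <- start(gr) + (width(gr) - 1L) %/% 2L
      as.logical(seqnames(gr) == as.character(seqnames(region))) &
        m >= start(region) & m <= end(region)
    } else {
      gr2 <- gr
      strand(gr2) <- "*"
      IRanges::overlapsAny(gr2, region, ignore.strand = TRUE)
    }
  }
  oneSet <- function(mirnas, dirs, label) {
    placed <- mirnas %in% names(loci)
    ins <- rep(NA, length(mirnas))
    ins[placed] <- insideOf(loci[mirnas[placed]])
    inside <- sum(ins, na.rm = TRUE)
    outside <- sum(!ins, na.rm = TRUE)
    data.frame(
      contrast = label, inside = inside, outside = outside,
      unplaced = sum(!placed), total = length(mirnas),
      pct = if (inside + outside > 0) .pct1(inside, inside + outside)
            else NA_real_,
      up_in = sum(ins & dirs == "up", na.rm = TRUE),
      up_out = sum(!ins & dirs == "up", na.rm = TRUE),
      down_in = sum(ins & dirs == "down", na.rm = TRUE),
      down_out = sum(!ins & dirs == "down", na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  cts <- unique(records$contrast)
  per <- do.call(rbind, lapply(cts, function(ct) {
    r <- records[records$contrast == ct, ]
    r <- r[!duplicated(r$mirna), ]
    oneSet(r$mirna, r$direction, ct)
  }))
  uni <- records[!duplicated(records$mirna), ]
  pooled <- oneSet(uni$mirna, uni$direction, "pooled")
  unplaced <- sort(unique(records$mirna[!records$mirna %in% names(loci)]))
  list(perContrast = per, pooled = pooled, unplaced = unplaced)
}

#' Region enrichment of DEMIRs (2x2 exact test)
#'
#' Tests whether DEMIRs fall inside the region more often than the
#' background miRNAs, with the conditional (hypergeometric) two-sided
#' exact test.  The odds ratio is the cross-product ratio; when any cell
#' is zero the Haldane correction (+0.5 to every cell) keeps it finite.
#'
#' @param insideDe,outsideDe DEMIR counts inside/outside the region.
#' @param insideBg,outsideBg Background (non-DE) counts inside/outside.
#' @return list(or, p, table).
#' @export
#' @examples
#' regionEnrichment(10, 5, 20, 100)
regionEnrichment <- function(insideDe, outsideDe, insideBg, outsideBg) {
  tab <- matrix(c(insideDe, outsideDe, insideBg, outsideBg), 2,
                byrow = TRUE,
                dimnames = list(c("DE", "background"),
                                c("inside", "outside")))
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margin in the 2x2 table")
  or <- if (any(tab == 0)) {
    (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  } else (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(or = unname(or), p = p, table = tab)
}
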