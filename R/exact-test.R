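## No-replicate differential expression for the pooled design: a
## conditional exact test on each count pair given its total, with the
## success probability set by the TMM-adjusted effective library sizes.
## With dispersion phi = 0 the conditional law is binomial; with phi > 0
## it is the distribution of X_a given X_a + X_b for independent
## negative binomials with null means proportional to the effective
## sizes, evaluated by direct summation over all splits of the total.

## two-sided p-values for all pairs of a contrast; tails include the
## observed point, smaller tail doubled, capped at 1.  phi = 0 is the
## conditional binomial (closed-form tails); phi > 0 sums the
## conditional NB mass over all splits of the total (compiled kernel).
.exactPvec <- function(xa, xb, na, nb, phi) {
  if (phi == 0) {
    n <- xa + xb
    p <- na / (na + nb)
    lower <- stats::pbinom(xa, n, p)
    upper <- stats::pbinom(xa - 1, n, p, lower.tail = FALSE)
    out <- pmin(1, 2 * pmin(lower, upper))
    out[n == 0] <- 1
    return(out)
  }
  .exactNbPvec(as.integer(xa), as.integer(xb), na, nb, phi)
}

## the DEMIR significance gate; both bounds inclusive
.demirGate <- function(qvalue, log2fc, qCut = 0.05, fcCut = 2) {
  qvalue <= qCut & abs(log2fc) >= log2(fcCut)
}

#' Exact test for one contrast of the no-replicate design
#'
#' Tests each miRNA for differential abundance between the two libraries
#' of \code{contrast} (\code{"numerator/denominator"}).  The p-value is
#' two-sided (doubled smaller tail of the conditional distribution of the
#' numerator count given the pair total, capped at 1); Benjamini-Hochberg
#' q-values are computed across all miRNAs of the contrast.  The log2
#' fold change uses effective-library-size-normalized counts with a
#' pseudo-count of 0.5.  A record is \code{significant} when
#' \code{qvalue <= qCut} and \code{|log2fc| >= log2(fcCut)} (both bounds
#' inclusive).
#'
#' @param x A \code{\linkS4class{MirCountSet}} or count matrix with the
#'   six group columns.
#' @param contrast Contrast label, e.g. \code{"MT/MP"}.
#' @param dispersion NB dispersion \eqn{\phi \ge 0} (fixed by
#'   configuration; a no-replicate design cannot estimate it).
#' @param factors TMM factors (default computed from \code{x}).
#' @param qCut,fcCut Significance gate: q-value cutoff (inclusive) and
#'   fold-change cutoff (inclusive, natural scale).
#' @return data.frame(mirna, contrast, log2fc, pvalue, qvalue,
#'   significant, direction).
#' @export
#' @examples
#' cnt <- matrix(rpois(60, 100), ncol = 6,
#'               dimnames = list(sprintf("miR-%02d", 1:10), groupLabels()))
#' head(exactTestPair(cnt, "MT/MP", dispersion = 0.05))
exactTestPair <- function(x, contrast, dispersion = 0.05,
                          factors = tmmFactors(x),
                          qCut = 0.05, fcCut = 2) {
  cnt <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
  if (dispersion < 0) stop("dispersion must be >= 0")
  gr <- strsplit(contrast, "/", fixed = TRUE)[[1]]
  if (length(gr) != 2 || !all(gr %in% colnames(cnt)))
    stop("unknown contrast: ", contrast)
  eff <- colSums(cnt) * factors[colnames(cnt)]
  na <- eff[gr[1]]; nb <- eff[gr[2]]
  xa <- cnt[, gr[1]]; xb <- cnt[, gr[2]]
  pvalue <- .exactPvec(xa, xb, na, nb, dispersion)
  log2fc <- log2((xa + 0.5) / na) - log2((xb + 0.5) / nb)
  qvalue <- stats::p.adjust(pvalue, method = "BH")
  significant <- .demirGate(qvalue, log2fc, qCut, fcCut)
  direction <- ifelse(!significant, "none",
                      ifelse(log2fc > 0, "up", "down"))
  data.frame(mirna = rownames(cnt), contrast = contrast,
             log2fc = unname(log2fc), pvalue = pvalue, qvalue = qvalue,
             significant = significant, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the exact test over a set of contrasts
#'
#' @inheritParams exactTestPair
#' @param contrasts Character vector of contrast labels (default: the six
#'   within-sex contrasts).
#' @return Row-bound \code{\link{exactTestPair}} records.
#' @export
runDE <- function(x, contrasts = withinSexContrasts(), dispersion = 0.05,
                  factors = tmmFactors(x), qCut = 0.05, fcCut = 2) {
  do.call(rbind, lapply(contrasts, function(ct)
    exactTestPair(x, ct, dispersion, factors, qCut, fcCut)))
}

#' Call differentially expressed miRNAs
#'
#' Filters the significant records and reports the DEMIR set: a miRNA is
#' a DEMIR when significant in at least one of the supplied contrasts.
#'
#' @param records \code{\link{runDE}} output (BH already applied per
#'   contrast).
#' @return list(records = significant records, demirs = character vector
#'   of DEMIR ids, perContrast = named list of per-contrast DEMIR id
#'   vectors).
#' @export
callDemirs <- function(records) {
  sig <- records[records$significant, , drop = FALSE]
  perContrast <- split(sig$mirna, sig$contrast)
  list(records = sig,
       demirs = sort(unique(sig$mirna)),
       perContrast = perContrast)
}

#' Relative expression by the delta-delta-Ct rule
#'
#' \eqn{2^{-(Ct_{miRNA} - Ct_{ref})}}: the qPCR abundance of the target
#' relative to the reference gene (Snord68 in the emulated assay).
#'
#' @param ctMirna,ctRef Finite Ct values (vectorized).
#' @return Relative expression.
#' @export
#' @examples
#' ddct(24, 25)  # 2.0
#' ddct(28, 25)  # 0.125
ddct <- function(ctMirna, ctRef) {
  stopifnot(all(is.finite(ctMirna)), all(is.finite(ctRef)))
  2^(-(ctMirna - ctRef))
}
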