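## TPM conversion and TMM between-library scaling for the six pooled
## libraries.

#' TPM normalization
#'
#' Converts raw counts to transcripts-per-million per library:
#' \eqn{tpm_{ig} = counts_{ig} \times 10^6 / \sum_j counts_{jg}}.
#' Every column of the result sums to \eqn{10^6}.
#'
#' @param x A \code{\linkS4class{MirCountSet}} or a count matrix.
#' @return Numeric matrix of TPM values, same dimensions as the counts.
#' @export
#' @examples
#' m <- matrix(c(10, 90, 40, 60), 2, dimnames = list(c("a", "b"), NULL))
#' tpmNormalize(m)
tpmNormalize <- function(x) {
  cnt <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
  tot <- colSums(cnt)
  if (any(tot <= 0)) stop("zero-total library: ",
                          paste(colnames(cnt)[tot <= 0], collapse = ", "))
  sweep(cnt, 2, tot, "/") * 1e6
}

## weighted trimmed mean of M-values for one library against the
## reference; the standard doubly-trimmed, inverse-variance-weighted
## estimator of the log ratio of effective library sizes.
.tmmOne <- function(obs, ref, nO, nR, trimM = 0.30, trimA = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) stop("no miRNA with positive counts in both libraries")
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trimM) + 1; hiL <- n + 1 - loL
  loS <- floor(n * trimA) + 1; hiS <- n + 1 - loS
  rL <- rank(logR); rS <- rank(absE)
  keep2 <- rL >= loL & rL <= hiL & rS >= loS & rS <= hiS
  f <- sum(logR[keep2] / v[keep2], na.rm = TRUE) /
    sum(1 / v[keep2], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM between-library scaling factors
#'
#' Trimmed-mean-of-M-values factors across the six libraries: for each
#' non-reference library, the factor is \eqn{2^{\bar M_w}} where
#' \eqn{\bar M_w} is the inverse-asymptotic-variance weighted mean of the
#' per-miRNA log2 count-rate ratios \eqn{M}, doubly trimmed (30\% on M,
#' 5\% on the average log abundance A); miRNAs with a zero in either
#' library are excluded.  Factors are rescaled to geometric mean 1.
#'
#' @param x A \code{\linkS4class{MirCountSet}} or count matrix
#'   (>= 2 columns).
#' @param refGroup Reference column name or index; default: the library
#'   whose total count is closest to the mean total.
#' @param trimM,trimA Trim fractions for M values and A values.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
#' @examples
#' m <- matrix(rpois(600, 100), ncol = 6,
#'             dimnames = list(NULL, groupLabels()))
#' tmmFactors(m)
tmmFactors <- function(x, refGroup = NULL, trimM = 0.30, trimA = 0.05) {
  cnt <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
  if (ncol(cnt) < 2) stop("need at least two libraries")
  tot <- colSums(cnt)
  if (any(tot <= 0)) stop("library with all-zero counts")
  if (is.null(refGroup)) refGroup <- which.min(abs(tot - mean(tot)))
  if (is.character(refGroup)) refGroup <- match(refGroup, colnames(cnt))
  f <- vapply(seq_len(ncol(cnt)), function(j) {
    if (j == refGroup) 1
    else .tmmOne(cnt[, j], cnt[, refGroup], tot[j], tot[refGroup],
                 trimM, trimA)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(cnt)
  f
}

#' Effective library sizes
#'
#' Library totals multiplied by their TMM factors; the sizes used by the
#' no-replicate exact test and for normalized fold changes.
#'
#' @param x A \code{\linkS4class{MirCountSet}} or count matrix.
#' @param factors Optional precomputed TMM factors (default
#'   \code{tmmFactors(x)}).
#' @return Named numeric vector of effective sizes.
#' @export
effectiveLibSizes <- function(x, factors = tmmFactors(x)) {
  cnt <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
  colSums(cnt) * factors
}
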