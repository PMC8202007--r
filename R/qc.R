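## Library-level quality control: correlation, PCA and saturation.

#' QC summaries of the six libraries
#'
#' Computes (i) the pairwise Pearson \eqn{R^2} matrix of
#' \eqn{\log_2(TPM+1)} profiles, (ii) the PCA coordinates of the
#' libraries (top three components of the centered \eqn{\log_2(TPM+1)}
#' matrix), and (iii) a sequencing-saturation curve: the number of
#' distinct miRNAs detected (count \eqn{\ge 1}) after nested binomial
#' thinning of each library to a grid of depth fractions.  Nested
#' thinning (each shallower subsample drawn from the previous one) makes
#' the curve monotone non-decreasing in depth by construction.
#'
#' @param x A \code{\linkS4class{MirCountSet}} or count matrix.
#' @param depthFractions Depth grid in (0, 1]; always augmented with 1.
#' @param seed Seed for the thinning draws.
#' @return list(r2 = R^2 matrix, pca = library x PC score matrix,
#'   pcaVar = proportion of variance per component, saturation =
#'   data.frame(fraction, group, detected), constant = TRUE when the
#'   profile matrix is constant and correlation undefined).
#' @export
#' @examples
#' cnt <- matrix(rpois(120, 80), ncol = 6,
#'               dimnames = list(sprintf("m%02d", 1:20), groupLabels()))
#' qc <- qcSummaries(cnt)
#' round(qc$r2, 2)
qcSummaries <- function(x, depthFractions = seq(0.1, 1, by = 0.1),
                        seed = 1L) {
  cnt <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
  lt <- log2(tpmNormalize(cnt) + 1)
  constant <- all(apply(lt, 1, stats::var) == 0)
  r2 <- if (constant) {
    matrix(NA_real_, ncol(lt), ncol(lt),
           dimnames = list(colnames(lt), colnames(lt)))
  } else stats::cor(lt)^2
  pc <- stats::prcomp(t(lt), center = TRUE, scale. = FALSE)
  k <- min(3, ncol(pc$x))
  pcaVar <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  ## nested thinning, deepest first
  fr <- sort(unique(c(depthFractions, 1)), decreasing = TRUE)
  stopifnot(all(fr >= 0 & fr <= 1))
  sat <- list()
  old <- .pushSeed(seed)
  on.exit(.popSeed(old), add = TRUE)
  for (g in colnames(cnt)) {
    cur <- cnt[, g]
    prev <- 1
    for (f in fr) {
      cur <- stats::rbinom(length(cur), cur, f / prev)
      prev <- f
      sat[[length(sat) + 1L]] <- data.frame(
        fraction = f, group = g, detected = sum(cur >= 1))
    }
  }
  sat <- do.call(rbind, sat)
  sat <- sat[order(sat$group, sat$fraction), ]
  rownames(sat) <- NULL
  list(r2 = r2, pca = pc$x[, seq_len(k), drop = FALSE], pcaVar = pcaVar,
       saturation = sat, constant = constant)
}
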