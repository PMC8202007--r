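## Seeded synthetic-data generator.  Emits every input the pipeline
## consumes -- counts, loci, target/TF-binding score tables, pathway
## sets, Ct values -- with planted ground truth, so each downstream
## stage has a recoverable answer key.  All randomness derives from
## config@seed; sub-generators use fixed offsets of it so the pieces
## can also be called independently and still reproduce.

.seedOffset <- c(counts = 0L, loci = 101L, edges = 202L, ct = 303L,
                 pathways = 404L)

.mirnaNames <- function(n) sprintf("miR-sim-%03d", seq_len(n))
.geneNames <- function(n) sprintf("G%04d", seq_len(n))
.tfNames <- function(n) sprintf("TF%02d", seq_len(n))

## expand the canonical planted-pattern spec (shared/M/F blocks) into
## data.frame(mirna, sex, subtype): the shared block occupies the head
## of the miRNA vector in both sexes, the sex-unique blocks follow on
## disjoint miRNAs
.plantedAssignments <- function(config, mirnas) {
  pp <- config@plantedPatterns
  expand <- function(v) rep(names(v), times = v)
  sSub <- expand(pp$shared); mSub <- expand(pp$M); fSub <- expand(pp$F)
  nS <- length(sSub); nM <- length(mSub); nF <- length(fSub)
  if (nS + nM + nF > length(mirnas))
    stop("more planted patterns than miRNAs")
  sMir <- mirnas[seq_len(nS)]
  mMir <- mirnas[nS + seq_len(nM)]
  fMir <- mirnas[nS + nM + seq_len(nF)]
  rbind(data.frame(mirna = c(sMir, mMir), sex = "M",
                   subtype = c(sSub, mSub), stringsAsFactors = FALSE),
        data.frame(mirna = c(sMir, fMir), sex = "F",
                   subtype = c(sSub, fSub), stringsAsFactors = FALSE))
}

#' Simulate the six-group miRNA count table
#'
#' Draws one negative-binomial count per miRNA per pooled library
#' (variance \eqn{\mu + \phi\mu^2}; Poisson at \eqn{\phi = 0}),
#' mirroring the no-replicate pooled design.  Baseline relative
#' abundances are log-normal; a planted miRNA with subtype grades
#' \eqn{(g_W, g_P, g_T)} has its group mean multiplied by
#' \eqn{fold^{g-1}} in the matching sex, so e.g. subtype \code{a1}
#' (T > P = W) at fold 8 gives \eqn{E[T] = 8 E[P] = 8 E[W]}.
#' Non-planted miRNAs share one mean across all six groups.
#'
#' @param config A \code{\linkS4class{SimConfig}}.
#' @return list(counts = \code{\linkS4class{MirCountSet}}, truth =
#'   \code{\linkS4class{GroundTruth}} (DEMIR and pattern slots filled),
#'   means = expected-count matrix).
#' @export
#' @examples
#' sim <- simulateCounts(simConfig(nMirna = 30, seed = 7))
#' sim$counts
simulateCounts <- function(config) {
  validObject(config)
  old <- .pushSeed(config@seed + .seedOffset[["counts"]])
  on.exit(.popSeed(old), add = TRUE)
  n <- config@nMirna
  mirnas <- .mirnaNames(n)
  w <- stats::rlnorm(n, config@baselineLogMean, config@baselineLogSd)
  planted <- .plantedAssignments(config, mirnas)
  mult <- matrix(1, n, 6, dimnames = list(mirnas, .GROUPS))
  for (i in seq_len(nrow(planted))) {
    g <- .SUBTYPE_GRADES[[planted$subtype[i]]]
    if (is.null(g)) g <- c(1, 1, 1)  # flat
    cols <- paste0(planted$sex[i], .TISSUES)
    mult[planted$mirna[i], cols] <- config@effectFold^(g - 1)
  }
  mu <- (w / sum(w)) %o% config@librarySizes * mult
  dimnames(mu) <- list(mirnas, .GROUPS)
  cnt <- matrix(0L, n, 6, dimnames = dimnames(mu))
  for (j in seq_len(6)) {
    cnt[, j] <- if (config@dispersion == 0) stats::rpois(n, mu[, j])
    else stats::rnbinom(n, mu = mu[, j], size = 1 / config@dispersion)
  }
  ## answer key: a planted contrast is truly differential when the
  ## grade step is non-trivial and the fold is > 1; sex-unique (or
  ## sex-divergent) patterns also create true between-sex differences
  demirs <- list()
  if (config@effectFold > 1) {
    for (i in seq_len(nrow(planted))) {
      g <- .SUBTYPE_GRADES[[planted$subtype[i]]]
      if (is.null(g)) next
      s <- planted$sex[i]
      steps <- list(c("T", "P"), c("T", "W"), c("P", "W"))
      for (st in steps) {
        gi <- g[match(st, c("W", "P", "T"))]
        if (gi[1] != gi[2])
          demirs[[length(demirs) + 1L]] <- data.frame(
            mirna = planted$mirna[i],
            contrast = paste0(s, st[1], "/", s, st[2]),
            direction = if (gi[1] > gi[2]) "up" else "down",
            stringsAsFactors = FALSE)
      }
    }
    gradeOf <- function(m, s, t) {
      row <- planted$subtype[planted$mirna == m & planted$sex == s]
      if (!length(row)) return(1)
      g <- .SUBTYPE_GRADES[[row[1]]]
      if (is.null(g)) 1 else g[match(t, c("W", "P", "T"))]
    }
    for (m in unique(planted$mirna)) for (t in .TISSUES) {
      gM <- gradeOf(m, "M", t); gF <- gradeOf(m, "F", t)
      if (gM != gF)
        demirs[[length(demirs) + 1L]] <- data.frame(
          mirna = m, contrast = paste0("M", t, "/F", t),
          direction = if (gM > gF) "up" else "down",
          stringsAsFactors = FALSE)
    }
  }
  trueDem <- if (length(demirs)) do.call(rbind, demirs) else
    data.frame(mirna = character(), contrast = character(),
               direction = character(), stringsAsFactors = FALSE)
  truePat <- planted
  if (config@effectFold <= 1) truePat$subtype <- "flat"
  truth <- new("GroundTruth", trueDemirs = trueDem, truePatterns = truePat,
               trueFfls = data.frame(tf = character(), mirna = character(),
                                     gene = character(),
                                     ffl_type = character(),
                                     stringsAsFactors = FALSE),
               inRegionMirnas = character())
  list(counts = MirCountSet(cnt), truth = truth, means = mu)
}

#' Simulate miRNA genomic loci
#'
#' Places exactly \code{round(fracInRegion * n)} locus midpoints inside
#' \code{config@region} (a seeded sample of the miRNAs); the remainder
#' go to other chromosomes.  Loci are short (default 80 bp) stranded
#' intervals.
#'
#' @param config A \code{\linkS4class{SimConfig}}.
#' @param mirnas Character vector of miRNA ids.
#' @param lociWidth Width of each simulated locus in bp.
#' @return list(loci = named \code{GRanges}, inRegion = character vector
#'   of in-region miRNA ids).
#' @export
simulateLoci <- function(config, mirnas, lociWidth = 80L) {
  region <- config@region
  if (width(region) <= 0) stop("empty region")
  old <- .pushSeed(config@seed + .seedOffset[["loci"]])
  on.exit(.popSeed(old), add = TRUE)
  n <- length(mirnas)
  nIn <- round(config@fracInRegion * n)
  if (nIn > 0 && width(region) < lociWidth + 2L)
    stop("region too small to host requested loci")
  inIdx <- if (nIn > 0) sort(sample(n, nIn)) else integer()
  chromIn <- as.character(seqnames(region))
  others <- setdiff(c(paste0("chr", 1:11), "chrX"), chromIn)
  chrom <- sample(others, n, replace = TRUE)
  ## uniform positions; in-region starts keep the whole locus inside
  startPos <- sample.int(1e8, n, replace = TRUE)
  chrom[inIdx] <- chromIn
  startPos[inIdx] <- start(region) +
    sample.int(width(region) - lociWidth, length(inIdx), replace = TRUE) - 1L
  gr <- GRanges(chrom, IRanges(start = startPos, width = lociWidth),
                strand = sample(c("+", "-"), n, replace = TRUE))
  names(gr) <- mirnas
  list(loci = gr, inRegion = mirnas[inIdx])
}

.passCs <- function(k) stats::runif(k, -1, -0.35)
.passTs <- function(k) stats::runif(k, 55, 95)
.passMx <- function(k) stats::runif(k, 0.96, 0.999)

#' Simulate target-prediction and TF-binding score tables
#'
#' Plants \code{config@nPlantedFfl} feed-forward loops per type on
#' disjoint (TF, miRNA, gene) triples, with scores on the passing side
#' of every threshold the network stage applies (context score < -0.3,
#' target score > 50, matrix score > 0.95, core score = 1.00).  Decoy
#' rows fail at least one threshold; optional passing noise edges close
#' no new triangle.  Because planted triples are node-disjoint and
#' decoys never become edges, downstream FFL recovery is exact.
#'
#' Planted miRNAs are assigned direction \code{up} and planted
#' genes/TFs \code{down}, so every planted miRNA edge survives the
#' anti-correlation constraint.
#'
#' @param config A \code{\linkS4class{SimConfig}}.
#' @param mirnas miRNA ids to draw FFL miRNAs from (planted loops use
#'   the head of this vector).
#' @param extraTargetMirnas miRNAs (e.g. in-region, sex-disparate ones)
#'   that additionally get threshold-passing target rows onto
#'   down-regulated genes carrying no TF edge, so they feed the
#'   over-representation stage without closing any feed-forward loop.
#' @return list(targets, tfbind, status, truth, extraGenes) where
#'   \code{status} is data.frame(name, class, direction, is_tf) for
#'   genes and TFs and \code{truth} is a \code{GroundTruth} with the
#'   FFL slot filled.
#' @export
simulateEdges <- function(config, mirnas = .mirnaNames(config@nMirna),
                          extraTargetMirnas = character()) {
  old <- .pushSeed(config@seed + .seedOffset[["edges"]])
  on.exit(.popSeed(old), add = TRUE)
  nf <- config@nPlantedFfl
  for (tp in .FFL_TYPES) if (is.na(nf[tp])) nf[tp] <- 0
  total <- sum(nf[.FFL_TYPES])
  if (total > config@nTf || total > config@nGene ||
      total > length(mirnas))
    stop("infeasible planting: need ", total,
         " disjoint TF/miRNA/gene triples")
  tfs <- .tfNames(config@nTf)
  genes <- .geneNames(config@nGene)
  types <- rep(.FFL_TYPES, times = nf[.FFL_TYPES])
  k <- length(types)
  tTf <- tfs[seq_len(k)]; tMir <- mirnas[seq_len(k)]
  tGene <- genes[seq_len(k)]
  targets <- list(); tfbind <- list()
  addT <- function(mirna, gene, cs, ts)
    data.frame(mirna = mirna, gene = gene, context_score = cs,
               target_score = ts, stringsAsFactors = FALSE)
  addB <- function(tf, target, cls, mx, core)
    data.frame(tf = tf, target = target, target_class = cls,
               matrix_score = mx, core_score = core,
               stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    targets[[length(targets) + 1L]] <-
      addT(tMir[i], tGene[i], .passCs(1), .passTs(1))
    tfbind[[length(tfbind) + 1L]] <-
      addB(tTf[i], tGene[i], "gene", .passMx(1), 1)
    if (types[i] %in% c("TF-FFL", "composite-FFL"))
      tfbind[[length(tfbind) + 1L]] <-
        addB(tTf[i], tMir[i], "mirna", .passMx(1), 1)
    if (types[i] %in% c("miRNA-FFL", "composite-FFL"))
      targets[[length(targets) + 1L]] <-
        addT(tMir[i], tTf[i], .passCs(1), .passTs(1))
  }
  ## decoys: random pairs with at least one score on the failing side
  nd <- config@nDecoy
  if (nd > 0) {
    half <- nd %/% 2
    dm <- sample(mirnas, half, replace = TRUE)
    dg <- sample(c(genes, tfs), half, replace = TRUE)
    failSide <- sample(3, half, replace = TRUE)  # 1 = cs, 2 = ts, 3 = both
    cs <- ifelse(failSide %in% c(1, 3), stats::runif(half, -0.29, 0),
                 .passCs(half))
    ts <- ifelse(failSide %in% c(2, 3), stats::runif(half, 0, 49),
                 .passTs(half))
    targets[[length(targets) + 1L]] <- addT(dm, dg, cs, ts)
    rest <- nd - half
    dt <- sample(tfs, rest, replace = TRUE)
    dgt <- sample(c(genes, mirnas), rest, replace = TRUE)
    fb <- sample(2, rest, replace = TRUE)
    mx <- ifelse(fb == 1, stats::runif(rest, 0.5, 0.95), .passMx(rest))
    core <- ifelse(fb == 2, stats::runif(rest, 0.5, 0.99), 1)
    core[fb == 1 & stats::runif(rest) < 0.5] <- 0.98  # some fail both
    tfbind[[length(tfbind) + 1L]] <-
      addB(dt, dgt, ifelse(dgt %in% mirnas, "mirna", "gene"), mx, core)
  }
  ## passing noise that closes no triangle: TF-gene edges onto genes
  ## with no miRNA edge, miRNA-gene edges onto genes with no TF edge
  if (config@noisePassing) {
    freeGenes <- setdiff(genes, tGene)
    nn <- min(10L, length(freeGenes) %/% 2)
    if (nn > 0) {
      gA <- freeGenes[seq_len(nn)]
      gB <- freeGenes[nn + seq_len(nn)]
      tfbind[[length(tfbind) + 1L]] <-
        addB(sample(tfs, nn, TRUE), gA, "gene", .passMx(nn), 1)
      targets[[length(targets) + 1L]] <-
        addT(sample(mirnas, nn, TRUE), gB, .passCs(nn), .passTs(nn))
    }
  }
  ## passing target rows for the designated miRNAs, onto genes with no
  ## TF edge (so no loop can close); those genes are marked down
  extraGenes <- character()
  if (length(extraTargetMirnas)) {
    pool <- utils::tail(setdiff(genes, tGene),
                        max(10L, min(30L, config@nGene - k)))
    for (m in extraTargetMirnas) {
      gs <- sample(pool, min(3L, length(pool)))
      extraGenes <- union(extraGenes, gs)
      targets[[length(targets) + 1L]] <-
        addT(m, gs, .passCs(length(gs)), .passTs(length(gs)))
    }
  }
  targets <- do.call(rbind, targets)
  tfbind <- do.call(rbind, tfbind)
  ## drop any decoy row that duplicates a planted pair, so planted
  ## scores stay authoritative
  targets <- targets[!duplicated(paste(targets$mirna, targets$gene)), ]
  tfbind <- tfbind[!duplicated(paste(tfbind$tf, tfbind$target)), ]
  dirGene <- stats::setNames(
    sample(c("up", "down"), config@nGene, replace = TRUE), genes)
  dirGene[tGene] <- "down"
  dirGene[extraGenes] <- "down"
  dirTf <- stats::setNames(
    sample(c("up", "down"), config@nTf, replace = TRUE), tfs)
  dirTf[tTf] <- "down"
  status <- rbind(
    data.frame(name = genes, class = "gene", direction = unname(dirGene),
               is_tf = FALSE, stringsAsFactors = FALSE),
    data.frame(name = tfs, class = "TF", direction = unname(dirTf),
               is_tf = TRUE, stringsAsFactors = FALSE))
  trueFfls <- data.frame(tf = tTf, mirna = tMir, gene = tGene,
                         ffl_type = types, stringsAsFactors = FALSE)
  truth <- new("GroundTruth",
               trueDemirs = data.frame(mirna = character(),
                                       contrast = character(),
                                       direction = character(),
                                       stringsAsFactors = FALSE),
               truePatterns = data.frame(mirna = character(),
                                         sex = character(),
                                         subtype = character(),
                                         stringsAsFactors = FALSE),
               trueFfls = trueFfls, inRegionMirnas = character())
  list(targets = targets, tfbind = tfbind, status = status,
       truth = truth, extraGenes = extraGenes)
}

#' Simulate a qPCR Ct table
#'
#' For each selected miRNA and library, \eqn{Ct = Ct_{ref} -
#' \log_2(a) + \epsilon} with \eqn{a} the relative abundance
#' (TPM / 1000, so typical values land near the reference) and
#' \eqn{\epsilon \sim N(0, noiseSd^2)}; the reference gene Ct is
#' constant.  A two-fold abundance difference therefore shifts
#' \eqn{\Delta Ct} by \eqn{-1}.
#'
#' @param config A \code{\linkS4class{SimConfig}}.
#' @param tpm TPM matrix (miRNA x group); default: computed from
#'   \code{simulateCounts(config)}.
#' @param mirnas miRNAs to assay (default: the first
#'   \code{nValidate} planted or overall miRNAs).
#' @param nValidate Number of miRNAs to assay when \code{mirnas} is
#'   \code{NULL} (default 6, as in the emulated validation).
#' @param ctRef Reference-gene Ct (constant).
#' @param noiseSd Gaussian Ct noise SD; 0 gives exact values.
#' @return data.frame(mirna, group, ct, ct_ref).
#' @export
simulateCt <- function(config, tpm = NULL, mirnas = NULL, nValidate = 6L,
                       ctRef = 25, noiseSd = 0.15) {
  if (is.null(tpm))
    tpm <- tpmNormalize(simulateCounts(config)$counts)
  if (is.null(mirnas)) mirnas <- utils::head(rownames(tpm), nValidate)
  old <- .pushSeed(config@seed + .seedOffset[["ct"]])
  on.exit(.popSeed(old), add = TRUE)
  sub <- tpm[mirnas, , drop = FALSE]
  a <- pmax(sub, 0.5) / 1e3
  ct <- ctRef - log2(a) +
    matrix(stats::rnorm(length(a), 0, noiseSd), nrow(a))
  data.frame(mirna = rep(mirnas, times = ncol(sub)),
             group = rep(colnames(sub), each = length(mirnas)),
             ct = as.vector(ct), ct_ref = ctRef,
             stringsAsFactors = FALSE)
}

#' Simulate pathway gene sets (GMT)
#'
#' Random gene sets over the gene universe plus, when \code{planted} is
#' given, one term enriched for the planted genes.
#'
#' @param config A \code{\linkS4class{SimConfig}}.
#' @param genes Gene universe.
#' @param planted Optional character vector to embed as an enriched term.
#' @param nTerms,sizeRange Number and size range of random terms.
#' @return Named list of gene sets.
#' @export
simulatePathways <- function(config, genes = .geneNames(config@nGene),
                             planted = NULL, nTerms = 20L,
                             sizeRange = c(10L, 40L)) {
  old <- .pushSeed(config@seed + .seedOffset[["pathways"]])
  on.exit(.popSeed(old), add = TRUE)
  sets <- lapply(seq_len(nTerms), function(i)
    sample(genes, sample(sizeRange[1]:sizeRange[2], 1)))
  names(sets) <- sprintf("PW%03d", seq_len(nTerms))
  if (!is.null(planted) && length(planted))
    sets$planted_pathway <- unique(c(planted,
                                     sample(genes, sizeRange[1])))
  sets
}

#' Run the whole generator
#'
#' Calls every sub-generator with seeds derived from \code{config@seed}
#' and merges their ground truths.  The planted FFL miRNAs are the head
#' of the miRNA vector, which is also where up-regulated (category a)
#' patterns are planted, so the stages compose.
#'
#' @param config A \code{\linkS4class{SimConfig}}.
#' @return list(counts, tpm, truth, loci, targets, tfbind, status,
#'   pathways, ct).
#' @export
#' @examples
#' sim <- simulateAll(simConfig(nMirna = 40, nGene = 60, nTf = 10,
#'                              seed = 3))
#' sim$truth
simulateAll <- function(config) {
  cs <- simulateCounts(config)
  mirnas <- rownames(assay(cs$counts, "counts"))
  lo <- simulateLoci(config, mirnas)
  ## in-region miRNAs with a sex-divergent planted pattern are the
  ## expected between-sex DEMIRs of the region; give them target rows
  ## so the over-representation stage has a recoverable query
  tp <- cs$truth@truePatterns
  perSex <- split(paste(tp$mirna, tp$subtype), tp$sex)
  divergent <- unique(tp$mirna[!(paste(tp$mirna, tp$subtype) %in%
                                   intersect(perSex$M, perSex$F))])
  ed <- simulateEdges(config, mirnas,
                      extraTargetMirnas = intersect(lo$inRegion,
                                                    divergent))
  tpm <- tpmNormalize(cs$counts)
  ct <- simulateCt(config, tpm = tpm)
  plantedGenes <- unique(c(ed$truth@trueFfls$gene, ed$extraGenes))
  pw <- simulatePathways(config, planted = plantedGenes)
  truth <- new("GroundTruth",
               trueDemirs = cs$truth@trueDemirs,
               truePatterns = cs$truth@truePatterns,
               trueFfls = ed$truth@trueFfls,
               inRegionMirnas = lo$inRegion)
  list(counts = cs$counts, tpm = tpm, truth = truth, loci = lo$loci,
       targets = ed$targets, tfbind = ed$tfbind, status = ed$status,
       pathways = pw, ct = ct)
}

#' Planted network fixture at the published scale
#'
#' Builds an edge network with exact per-relation edge counts and
#' per-class node counts in which \emph{every} edge lies on at least one
#' feed-forward loop, so the FFL-union summary reports exactly the
#' requested totals.  The default arguments reproduce the accounting of
#' the emulated study's common regulatory network: 461 miRNA-gene + 4
#' miRNA-TF + 588 TF-gene + 129 TF-miRNA = 1,182 edges over 265 genes +
#' 46 miRNAs + 15 TFs = 326 nodes.
#'
#' Construction: a universal TF and a universal miRNA cover every gene;
#' all remaining TF-gene edges target a common gene block that every
#' secondary TF also regulates via the universal miRNA; every secondary
#' miRNA targets genes within that block and is regulated by the
#' universal TF.  Feasibility of the requested counts is checked.
#'
#' @param nGene,nMirna,nTf Node counts per class.
#' @param nMg,nMt,nTg,nTm Edge counts: miRNA-gene, miRNA-TF, TF-gene,
#'   TF-miRNA.
#' @return Edge data.frame(source, target, relation).
#' @export
simulateNetworkFixture <- function(nGene = 265L, nMirna = 46L, nTf = 15L,
                                   nMg = 461L, nMt = 4L, nTg = 588L,
                                   nTm = 129L) {
  genes <- .geneNames(nGene); mirs <- .mirnaNames(nMirna)
  tfs <- .tfNames(nTf)
  u <- function(src, tgt, rel) data.frame(source = src, target = tgt,
                                          relation = rel,
                                          stringsAsFactors = FALSE)
  e <- list()
  ## universal TF t1 and miRNA m1 cover every gene
  e$tg1 <- u(tfs[1], genes, "TF-gene")
  e$mg1 <- u(mirs[1], genes, "miRNA-gene")
  tmLeft <- nTm - 1L            # t1 -> m1
  tgLeft <- nTg - nGene
  mgLeft <- nMg - nGene
  secTf <- tfs[-1]; secMir <- mirs[-1]
  if (tgLeft < 0 || mgLeft < 0 ||
      tmLeft < length(secMir) + length(secTf))
    stop("infeasible edge/node counts for the covering construction")
  ## secondary TFs regulate a common gene block (plus remainder edges)
  per <- tgLeft %/% length(secTf)
  extra <- tgLeft %% length(secTf)
  if (per < 1) stop("too few TF-gene edges for the TF count")
  block <- genes[seq_len(per + (extra > 0))]
  tg2 <- do.call(rbind, lapply(seq_along(secTf), function(i) {
    kk <- per + (i <= extra)
    u(secTf[i], genes[seq_len(kk)], "TF-gene")
  }))
  e$tg2 <- tg2
  ## secondary miRNAs target genes inside the common block
  if (mgLeft < length(secMir)) stop("too few miRNA-gene edges")
  perM <- mgLeft %/% length(secMir)
  extraM <- mgLeft %% length(secMir)
  mg2 <- do.call(rbind, lapply(seq_along(secMir), function(i) {
    kk <- perM + (i <= extraM)
    u(secMir[i], genes[((seq_len(kk) - 1L) %% per) + 1L], "miRNA-gene")
  }))
  e$mg2 <- mg2
  ## TF-miRNA: t1 -> every miRNA; every secondary TF -> m1; remainder
  ## secondary TF x secondary miRNA pairs
  tm <- rbind(u(tfs[1], mirs, "TF-miRNA"),
              u(secTf, mirs[1], "TF-miRNA"))
  need <- nTm - nrow(tm)
  if (need < 0) stop("too few TF-miRNA edges for the construction")
  if (need > 0) {
    grid <- expand.grid(tf = secTf, m = secMir, stringsAsFactors = FALSE)
    tm <- rbind(tm, u(grid$tf[seq_len(need)], grid$m[seq_len(need)],
                      "TF-miRNA"))
  }
  e$tm <- tm
  ## miRNA-TF edges between secondary miRNAs and secondary TFs
  if (nMt > 0) {
    grid <- expand.grid(m = secMir[seq_len(min(4, length(secMir)))],
                        tf = secTf[seq_len(min(4, length(secTf)))],
                        stringsAsFactors = FALSE)
    if (nMt > nrow(grid)) stop("too many miRNA-TF edges requested")
    e$mt <- u(grid$m[seq_len(nMt)], grid$tf[seq_len(nMt)], "miRNA-TF")
  }
  out <- .dedupeEdges(do.call(rbind, e))
  rownames(out) <- NULL
  stopifnot(nrow(out) == nMg + nMt + nTg + nTm)
  out
}
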