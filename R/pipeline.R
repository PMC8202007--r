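## End-to-end orchestration: one configuration drives
## simulate/read -> normalize -> exact tests -> pattern grading ->
## FFL network -> region localization -> over-representation, with a
## machine-readable run report of the counts at every stage.

#' Default run configuration
#'
#' Returns the full configuration list with every threshold at its
#' documented default (the published parameterization): q <= 0.05,
#' fold change >= 2, context score < -0.3, target score > 50, matrix
#' score > 0.95, core score = 1.00, hub quantile 0.25, recurrence
#' minimum 2, dispersion 0.05.  Flags: \code{targetsMode}
#' (intersection/union), \code{minSigMode} (pooled/per-sex),
#' \code{regionMode} (midpoint/overlap), \code{directionFirst} (apply
#' the anti-correlation constraint before FFL enumeration),
#' \code{vennAfterFilter} (Venn counts after the recurrence filter),
#' \code{allowSelf}.
#'
#' @param seed Integer seed.
#' @param inputDir Directory with pipeline inputs (as written by
#'   \code{\link{writeSimulation}}); \code{NULL} simulates in memory.
#' @param ... Overrides for any configuration entry.
#' @return Named list.
#' @export
#' @examples
#' str(defaultRunConfig(seed = 2), max.level = 1)
defaultRunConfig <- function(seed = 1L, inputDir = NULL, ...) {
  cfg <- list(
    inputDir = inputDir, seed = as.integer(seed),
    qCut = 0.05, fcCut = 2, csCut = -0.3, tsCut = 50,
    matrixCut = 0.95, coreReq = 1.00, hubQuantile = 0.25,
    minSig = 2L, dispersion = 0.05, minOverlap = 3L,
    region = list(chrom = "chr12", start = 109540001, end = 110000000,
                  label = "Dlk1-Dio3 GIR, chr12qF1"),
    targetsMode = "intersection", minSigMode = "pooled",
    regionMode = "midpoint", directionFirst = TRUE,
    vennAfterFilter = FALSE, allowSelf = FALSE,
    sim = list(nMirna = 300L, nGene = 400L, nTf = 30L,
               librarySize = 1e7, dispersion = 0.05, effectFold = 8,
               fracInRegion = 0.5))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read / write a run configuration as YAML
#'
#' \code{readRunConfig} merges the file over
#' \code{\link{defaultRunConfig}}, so a bare file reproduces the default
#' parameterization.
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return \code{readRunConfig}: configuration list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  for (nm in names(y)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(y[[nm]])) {
      utils::modifyList(cfg[[nm]], y[[nm]])
    } else y[[nm]]
  }
  cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.regionGRanges <- function(region) {
  if (is(region, "GRanges")) return(region)
  gr <- GRanges(region$chrom,
                IRanges(start = region$start, end = region$end))
  names(gr) <- region$label %||% "region"
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.simConfigFrom <- function(config) {
  s <- config$sim
  simConfig(nMirna = s$nMirna %||% 300L, nGene = s$nGene %||% 400L,
            nTf = s$nTf %||% 30L,
            librarySizes = stats::setNames(
              rep(s$librarySize %||% 1e7, 6), groupLabels()),
            dispersion = s$dispersion %||% config$dispersion,
            effectFold = s$effectFold %||% 8,
            region = .regionGRanges(config$region),
            fracInRegion = s$fracInRegion %||% 0.5,
            seed = config$seed)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes every stage on either a simulated data set (default) or the
#' files under \code{config$inputDir}, optionally writing all stage
#' outputs and a JSON run report to \code{outDir}.  The run is
#' deterministic given the configuration and seed.
#'
#' @param config Configuration list (see \code{\link{defaultRunConfig}}).
#' @param outDir Optional output directory.
#' @return list(report, demirs, records, patterns, sharedUnique, venn,
#'   edges, ffls, snws, hubs, gir, enrichment, qc, truth (when
#'   simulated), sim inputs).
#' @export
#' @examples
#' cfg <- defaultRunConfig(seed = 1)
#' cfg$sim$nMirna <- 60; cfg$sim$librarySize <- 2e5
#' res <- runPipeline(cfg)
#' res$report$de$n_demirs_within
runPipeline <- function(config = defaultRunConfig(), outDir = NULL) {
  region <- .regionGRanges(config$region)
  ## ---- inputs -------------------------------------------------------
  truth <- NULL
  if (is.null(config$inputDir)) {
    sim <- .stage("simulate", simulateAll(.simConfigFrom(config)))
    counts <- sim$counts; loci <- sim$loci; targets <- sim$targets
    tfbind <- sim$tfbind; status <- sim$status; pathways <- sim$pathways
    ct <- sim$ct; truth <- sim$truth
    if (!is.null(outDir)) writeSimulation(sim, file.path(outDir, "inputs"))
  } else {
    d <- config$inputDir
    counts <- .stage("read", readCounts(file.path(d, "counts.tsv")))
    loci <- .stage("read", readLoci(file.path(d, "loci.bed")))
    targets <- .stage("read", readTargets(file.path(d, "targets.tsv")))
    tfbind <- .stage("read", readTfBind(file.path(d, "tfbind.tsv")))
    status <- .stage("read", readStatus(file.path(d, "status.tsv")))
    pathways <- .stage("read", readGmt(file.path(d, "pathways.gmt")))
    ct <- .stage("read", readCt(file.path(d, "ct.tsv")))
    tp <- file.path(d, "truth.json")
    if (file.exists(tp)) truth <- readTruth(tp)
  }
  ## ---- de -----------------------------------------------------------
  factors <- .stage("de", tmmFactors(counts))
  tpm <- .stage("de", tpmNormalize(counts))
  records <- .stage("de", runDE(
    counts, c(withinSexContrasts(), betweenSexContrasts()),
    dispersion = config$dispersion, factors = factors,
    qCut = config$qCut, fcCut = config$fcCut))
  within <- records[records$contrast %in% withinSexContrasts(), ]
  between <- records[records$contrast %in% betweenSexContrasts(), ]
  demWithin <- callDemirs(within)
  demBetween <- callDemirs(between)
  qc <- .stage("qc", qcSummaries(counts, seed = config$seed))
  ## ---- patterns -----------------------------------------------------
  pats <- .stage("patterns", rbind(
    gradePatterns(within[within$contrast %in% withinSexContrasts("M"), ], "M"),
    gradePatterns(within[within$contrast %in% withinSexContrasts("F"), ], "F")))
  patsKept <- .stage("patterns", filterRecurrent(
    pats, minSig = config$minSig, mode = config$minSigMode))
  shared <- .stage("patterns", callSharedUnique(patsKept))
  venn <- .stage("patterns", vennCounts(
    if (config$vennAfterFilter)
      within[within$mirna %in% unique(patsKept$mirna), ] else within))
  ## ---- ffl ----------------------------------------------------------
  tfGenes <- status$name[status$is_tf]
  mirEdges <- .stage("ffl", buildMirnaTargets(
    targets, tfGenes = tfGenes, csCut = config$csCut,
    tsCut = config$tsCut, mode = config$targetsMode))
  tfEdges <- .stage("ffl", buildTfEdges(
    tfbind, matrixCut = config$matrixCut, coreReq = config$coreReq))
  edges <- rbind(mirEdges[c("source", "target", "relation")],
                 tfEdges[c("source", "target", "relation")])
  ## miRNA directions from the pattern categories; gene/TF directions
  ## from the status table
  mirCat <- ifelse(shared$male_category != "none", shared$male_category,
                   shared$female_category)
  mirnaDir <- stats::setNames(directionOfCategory(mirCat), shared$mirna)
  targetDir <- stats::setNames(status$direction, status$name)
  dropped <- c(same_direction = 0L, unannotated = 0L)
  if (config$directionFirst) {
    dc <- .stage("ffl", applyDirectionConstraint(edges, mirnaDir, targetDir))
    edges <- dc$edges; dropped <- dc$dropped
  }
  enum <- .stage("ffl", enumerateFFLs(edges, allowSelf = config$allowSelf))
  if (!config$directionFirst && nrow(enum$ffls)) {
    dc <- .stage("ffl", applyDirectionConstraint(edges, mirnaDir, targetDir))
    kept <- paste(dc$edges$source, dc$edges$target) |> unique()
    ok <- paste(enum$ffls$mirna, enum$ffls$gene) %in% kept
    enum$ffls <- enum$ffls[ok, , drop = FALSE]
    enum$summary <- fflSummary(enum$ffls, dc$edges)
    dropped <- dc$dropped
  }
  snws <- .stage("ffl", buildSubnetworks(enum$ffls, edges))
  hubs <- if (nrow(snwNodes(snws[["TF-SNW"]])))
    .stage("ffl", suppressWarnings(
      extractHubs(snws[["TF-SNW"]], quantile = config$hubQuantile)))
  else NULL
  ## ---- gir ----------------------------------------------------------
  gir <- .stage("gir", locateInRegion(
    demBetween$records, loci, region, mode = config$regionMode))
  bgAll <- names(loci)
  bgIn <- sum(as.logical(seqnames(loci) == as.character(seqnames(region))) &
                (start(loci) + (width(loci) - 1L) %/% 2L) >= start(region) &
                (start(loci) + (width(loci) - 1L) %/% 2L) <= end(region))
  de <- gir$pooled
  girTest <- if (de$inside + de$outside > 0 &&
                 length(bgAll) > de$inside + de$outside) {
    .stage("gir", regionEnrichment(
      de$inside, de$outside,
      bgIn - de$inside, length(bgAll) - bgIn - de$outside))
  } else NULL
  ## ---- enrichment ---------------------------------------------------
  downGenes <- status$name[status$direction == "down" & !status$is_tf]
  inRegionDem <- intersect(demBetween$demirs, {
    m <- start(loci) + (width(loci) - 1L) %/% 2L
    names(loci)[as.logical(seqnames(loci) ==
                             as.character(seqnames(region))) &
                  m >= start(region) & m <= end(region)]
  })
  query <- .stage("enrich", targetsOfRegionMirnas(
    inRegionDem, mirEdges, downGenes))
  enr <- if (length(query)) {
    .stage("enrich", ora(query, downGenes, pathways,
                         minOverlap = config$minOverlap))
  } else NULL
  ## ---- report -------------------------------------------------------
  catCounts <- table(factor(patsKept$category,
                            levels = unique(.SUBTYPE_CATEGORY)))
  report <- list(
    seed = config$seed,
    de = list(
      n_mirna = nrow(counts),
      tmm_factors = as.list(round(factors, 4)),
      n_demirs_within = length(demWithin$demirs),
      n_demirs_between = length(demBetween$demirs),
      demirs_per_contrast = lapply(
        split(records$mirna[records$significant],
              records$contrast[records$significant]), length)),
    patterns = list(
      n_recurrent = length(unique(patsKept$mirna)),
      category_counts = as.list(catCounts),
      shared = sum(shared$status == "shared"),
      male_unique = sum(shared$status == "male-unique"),
      female_unique = sum(shared$status == "female-unique"),
      discordant = sum(shared$status == "discordant")),
    ffl = c(enum$summary,
            list(dropped_edges = as.list(dropped),
                 hubs = if (is.null(hubs)) 0L else nrow(hubs$hubs))),
    gir = list(per_contrast = gir$perContrast, pooled = gir$pooled,
               n_unplaced = length(gir$unplaced),
               enrichment = if (is.null(girTest)) NULL else
                 list(or = girTest$or, p = girTest$p)),
    enrichment = list(
      query_size = length(query),
      n_terms_tested = if (is.null(enr)) 0L else nrow(enr),
      top_term = if (!is.null(enr) && nrow(enr)) enr$term[1] else NA))
  res <- list(report = report, records = records,
              demirsWithin = demWithin, demirsBetween = demBetween,
              patterns = pats, patternsKept = patsKept,
              sharedUnique = shared, venn = venn, edges = edges,
              ffls = enum$ffls, fflSummary = enum$summary, snws = snws,
              hubs = hubs, gir = gir, girTest = girTest,
              enrichment = enr, qc = qc, tpm = tpm, factors = factors,
              ct = ct, truth = truth)
  if (!is.null(outDir)) .writeOutputs(res, outDir)
  res
}

## write every stage output under outDir
.writeOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  .writeTsv(res$records[res$records$significant, ], p("demirs.tsv"))
  .writeTsv(data.frame(mirna = rownames(res$tpm), res$tpm,
                       check.names = FALSE), p("norm.tsv"))
  .writeTsv(res$patterns, p("patterns.tsv"))
  jsonlite::write_json(res$venn, p("venn.json"), auto_unbox = TRUE)
  .writeTsv(res$ffls, p("ffls.tsv"))
  nodes <- do.call(rbind, lapply(names(res$snws), function(nm) {
    nt <- snwNodes(res$snws[[nm]])
    if (nrow(nt)) cbind(snw = nm, nt) else NULL
  }))
  if (!is.null(nodes)) {
    if (!is.null(res$hubs))
      nodes$hub <- nodes$node %in% res$hubs$hubs$node & nodes$snw == "TF-SNW"
    .writeTsv(nodes, p("snw_nodes.tsv"))
  }
  .writeTsv(rbind(res$gir$perContrast, res$gir$pooled),
            p("gir_summary.tsv"))
  if (!is.null(res$enrichment))
    .writeTsv(res$enrichment, p("enrichment.tsv"))
  jsonlite::write_json(res$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(res$fflSummary, p("summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}
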