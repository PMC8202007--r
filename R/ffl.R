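## miRNA-TF-gene regulatory network assembly and 3-node feed-forward
## loop (FFL) enumeration.
##
## Four typed relations are assembled from score tables: miRNA-gene and
## miRNA-TF (sequence-based target prediction, kept when the pair passes
## the context-score gate in one source AND the target-score gate in the
## other), TF-gene and TF-miRNA (promoter binding-site scan, kept at
## core score 1.00 and matrix score > 0.95).  A 3-node FFL is a triple
## (TF, miRNA, gene) with TF->gene, miRNA-|gene, and at least one of
## TF->miRNA / miRNA-|TF; the three FFL types are mutually exclusive by
## which of those two edges exist.

.RELATIONS <- c("miRNA-gene", "miRNA-TF", "TF-gene", "TF-miRNA")
.FFL_TYPES <- c("TF-FFL", "miRNA-FFL", "composite-FFL")

.edgeKey <- function(e) paste(e$source, e$target, e$relation, sep = "\r")

.dedupeEdges <- function(edges) edges[!duplicated(.edgeKey(edges)), ,
                                      drop = FALSE]

.emptyEdges <- function() data.frame(
  source = character(), target = character(), relation = character(),
  stringsAsFactors = FALSE)

#' miRNA-target edges from paired prediction scores
#'
#' Keeps a (miRNA, gene) pair when it passes the total-context-score
#' gate (\code{context_score < csCut}, strict) in the first source and
#' the target-score gate (\code{target_score > tsCut}, strict) in the
#' second — intersection semantics, i.e. the pair must be supported by
#' both sources.  \code{mode = "union"} instead keeps pairs passing
#' either gate.  Pairs whose target is in \code{tfGenes} are emitted
#' twice: as \code{miRNA-gene} and as \code{miRNA-TF}.
#'
#' @param targets data.frame(mirna, gene, context_score, target_score);
#'   \code{NA} in a score column means the pair is absent from that
#'   source.
#' @param tfGenes Character vector of TF-flagged gene names.
#' @param csCut Context-score threshold (default -0.3; keep strictly
#'   below).
#' @param tsCut Target-score threshold (default 50; keep strictly above).
#' @param mode \code{"intersection"} (default) or \code{"union"}.
#' @return Edge data.frame(source, target, relation, context_score,
#'   target_score).
#' @export
#' @examples
#' tg <- data.frame(mirna = "miR-1", gene = "Apoa5",
#'                  context_score = -0.31, target_score = 51)
#' buildMirnaTargets(tg)
buildMirnaTargets <- function(targets, tfGenes = character(),
                              csCut = -0.3, tsCut = 50,
                              mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  .needCols(targets, c("mirna", "gene", "context_score", "target_score"),
            "target table")
  if (any(!is.na(targets$target_score) &
          (targets$target_score < 0 | targets$target_score > 100)))
    stop("malformed target_score (outside 0-100)")
  passCs <- !is.na(targets$context_score) & targets$context_score < csCut
  passTs <- !is.na(targets$target_score) & targets$target_score > tsCut
  keep <- if (mode == "intersection") passCs & passTs else passCs | passTs
  kept <- targets[keep, , drop = FALSE]
  kept <- kept[kept$mirna != kept$gene, , drop = FALSE]
  base <- data.frame(source = kept$mirna, target = kept$gene,
                     relation = rep("miRNA-gene", nrow(kept)),
                     context_score = kept$context_score,
                     target_score = kept$target_score,
                     stringsAsFactors = FALSE)
  isTf <- base$target %in% tfGenes
  if (any(isTf)) {
    dup <- base[isTf, , drop = FALSE]
    dup$relation <- "miRNA-TF"
    base <- rbind(base, dup)
  }
  .dedupeEdges(base)
}

#' TF edges from binding-site scan scores
#'
#' Keeps a scanned (TF, target) pair when \code{core_score == coreReq}
#' and \code{matrix_score > matrixCut} (strict).  The relation comes
#' from \code{target_class} (\code{"gene"} -> TF-gene, \code{"mirna"} ->
#' TF-miRNA); self-pairs are dropped.
#'
#' @param scan data.frame(tf, target, target_class, matrix_score,
#'   core_score).
#' @param matrixCut Matrix-score threshold (default 0.95, strict).
#' @param coreReq Required core score (default 1.00, equality).
#' @return Edge data.frame(source, target, relation, matrix_score,
#'   core_score).
#' @export
buildTfEdges <- function(scan, matrixCut = 0.95, coreReq = 1.00) {
  .needCols(scan, c("tf", "target", "target_class", "matrix_score",
                    "core_score"), "TF scan table")
  bad <- setdiff(unique(scan$target_class), c("gene", "mirna"))
  if (length(bad)) stop("unknown target_class: ", paste(bad, collapse = ", "))
  keep <- scan$core_score == coreReq & scan$matrix_score > matrixCut
  kept <- scan[keep, , drop = FALSE]
  kept <- kept[kept$tf != kept$target, , drop = FALSE]
  out <- data.frame(source = kept$tf, target = kept$target,
                    relation = ifelse(kept$target_class == "gene",
                                      "TF-gene", "TF-miRNA"),
                    matrix_score = kept$matrix_score,
                    core_score = kept$core_score,
                    stringsAsFactors = FALSE)
  .dedupeEdges(out)
}

#' Anti-correlation constraint on miRNA edges
#'
#' Since miRNAs repress their targets, a \code{miRNA-gene} or
#' \code{miRNA-TF} edge is biologically plausible only when the miRNA
#' and its target changed in opposite directions; edges whose endpoints
#' share a direction, and edges with an unannotated endpoint, are
#' dropped (the latter counted, never silently).  TF edges pass
#' unconstrained.
#'
#' @param edges Edge data.frame.
#' @param mirnaDir Named character vector miRNA -> \code{"up"}/\code{"down"}.
#' @param targetDir Named character vector gene/TF -> direction.
#' @return list(edges = retained edges, dropped = named counts
#'   \code{c(same_direction, unannotated)}).
#' @export
applyDirectionConstraint <- function(edges, mirnaDir, targetDir) {
  isMir <- edges$relation %in% c("miRNA-gene", "miRNA-TF")
  md <- unname(mirnaDir[edges$source])
  gd <- unname(targetDir[edges$target])
  unann <- isMir & (is.na(md) | is.na(gd))
  same <- isMir & !unann & md == gd
  keep <- !isMir | (!unann & md != gd)
  list(edges = edges[keep, , drop = FALSE],
       dropped = c(same_direction = sum(same), unannotated = sum(unann)))
}

#' Enumerate and type 3-node feed-forward loops
#'
#' Finds every (TF, miRNA, gene) triple with edges TF->gene AND
#' miRNA-|gene AND (TF->miRNA OR miRNA-|TF), typed by the mutually
#' exclusive rule: both cross edges -> \code{composite-FFL}; only
#' TF->miRNA -> \code{TF-FFL}; only miRNA-|TF -> \code{miRNA-FFL}.
#'
#' @param edges Edge data.frame (deduplicated internally).
#' @param allowSelf Keep triples where the TF is its own target gene
#'   (default \code{FALSE}).
#' @return list(ffls = data.frame(tf, mirna, gene, ffl_type), summary =
#'   the \code{\link{fflSummary}} of the result).
#' @export
#' @examples
#' e <- data.frame(source = c("TF1", "TF1", "miR-1"),
#'                 target = c("miR-1", "G1", "G1"),
#'                 relation = c("TF-miRNA", "TF-gene", "miRNA-gene"))
#' enumerateFFLs(e)$ffls
enumerateFFLs <- function(edges, allowSelf = FALSE) {
  edges <- .dedupeEdges(edges)
  tg <- edges[edges$relation == "TF-gene", c("source", "target")]
  mg <- edges[edges$relation == "miRNA-gene", c("source", "target")]
  tm <- edges[edges$relation == "TF-miRNA", c("source", "target")]
  mt <- edges[edges$relation == "miRNA-TF", c("source", "target")]
  empty <- data.frame(tf = character(), mirna = character(),
                      gene = character(), ffl_type = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(tg) || !nrow(mg)) {
    return(list(ffls = empty, summary = fflSummary(empty, edges)))
  }
  names(tg) <- c("tf", "gene"); names(mg) <- c("mirna", "gene")
  cand <- merge(tg, mg, by = "gene")
  if (!allowSelf) cand <- cand[cand$tf != cand$gene, , drop = FALSE]
  tmKey <- paste(tm$source, tm$target, sep = "\r")
  mtKey <- paste(mt$source, mt$target, sep = "\r")
  hasTm <- paste(cand$tf, cand$mirna, sep = "\r") %in% tmKey
  hasMt <- paste(cand$mirna, cand$tf, sep = "\r") %in% mtKey
  keep <- hasTm | hasMt
  ffls <- data.frame(tf = cand$tf[keep], mirna = cand$mirna[keep],
                     gene = cand$gene[keep],
                     ffl_type = ifelse(hasTm[keep] & hasMt[keep],
                                       "composite-FFL",
                                       ifelse(hasTm[keep], "TF-FFL",
                                              "miRNA-FFL")),
                     stringsAsFactors = FALSE)
  ffls <- ffls[order(ffls$tf, ffls$mirna, ffls$gene), , drop = FALSE]
  rownames(ffls) <- NULL
  list(ffls = ffls, summary = fflSummary(ffls, edges))
}

## edges of the FFL union, one row per (source, target, relation)
.fflUnionEdges <- function(ffls, edges) {
  if (!nrow(ffls)) return(.emptyEdges())
  tmKey <- .edgeKey(data.frame(source = ffls$tf, target = ffls$mirna,
                               relation = "TF-miRNA"))
  mtKey <- .edgeKey(data.frame(source = ffls$mirna, target = ffls$tf,
                               relation = "miRNA-TF"))
  present <- .edgeKey(edges)
  used <- unique(c(
    .edgeKey(data.frame(source = ffls$tf, target = ffls$gene,
                        relation = "TF-gene")),
    .edgeKey(data.frame(source = ffls$mirna, target = ffls$gene,
                        relation = "miRNA-gene")),
    intersect(tmKey, present), intersect(mtKey, present)))
  parts <- do.call(rbind, strsplit(used, "\r", fixed = TRUE))
  data.frame(source = parts[, 1], target = parts[, 2],
             relation = parts[, 3], stringsAsFactors = FALSE)
}

#' Accounting summary of an FFL set
#'
#' Reports, over the union of edges that participate in at least one
#' FFL: the FFL count (total and per type), the unique edge count (total
#' and per relation), and the unique node count (total and per class).
#'
#' @param ffls data.frame(tf, mirna, gene, ffl_type).
#' @param edges The edge set the FFLs were enumerated from (used to know
#'   which of TF->miRNA / miRNA-|TF closes each loop).
#' @return Nested list with components \code{ffl}, \code{edges},
#'   \code{nodes}, each holding a total and a per-type breakdown.
#' @export
fflSummary <- function(ffls, edges) {
  un <- .fflUnionEdges(ffls, edges)
  relCount <- vapply(.RELATIONS, function(r) sum(un$relation == r), 0L)
  typeCount <- vapply(.FFL_TYPES, function(t) sum(ffls$ffl_type == t), 0L)
  nodes <- list(TF = unique(ffls$tf), miRNA = unique(ffls$mirna),
                gene = unique(ffls$gene))
  list(
    ffl = list(total = nrow(ffls), by_type = as.list(typeCount)),
    edges = list(total = nrow(un), by_relation = as.list(relCount)),
    nodes = list(total = length(unique(unlist(nodes))),
                 by_class = lapply(nodes, length)))
}

## node table (node, class, degree) of an edge set; class from role
.nodeTable <- function(edges, classOf) {
  all <- c(edges$source, edges$target)
  if (!length(all))
    return(data.frame(node = character(), class = character(),
                      degree = integer(), stringsAsFactors = FALSE))
  deg <- table(all)
  data.frame(node = names(deg), class = unname(classOf[names(deg)]),
             degree = as.integer(deg), stringsAsFactors = FALSE,
             row.names = NULL)
}

## class of each node implied by the relations it appears in
.classOfNodes <- function(edges) {
  cls <- character()
  add <- function(cls, nm, cl) {
    new <- setdiff(nm, names(cls))
    c(cls, stats::setNames(rep(cl, length(new)), new))
  }
  cls <- add(cls, edges$source[edges$relation %in% c("TF-gene", "TF-miRNA")],
             "TF")
  cls <- add(cls, edges$target[edges$relation == "miRNA-TF"], "TF")
  cls <- add(cls, edges$source[edges$relation %in% c("miRNA-gene", "miRNA-TF")],
             "miRNA")
  cls <- add(cls, edges$target[edges$relation == "TF-miRNA"], "miRNA")
  cls <- add(cls, edges$target[edges$relation %in% c("TF-gene", "miRNA-gene")],
             "gene")
  cls
}

#' Build the per-type FFL sub-networks
#'
#' Groups the FFLs by type and assembles, for each type, the sub-network
#' (SNW) of their union edges with typed, degree-annotated nodes.
#'
#' @param ffls data.frame(tf, mirna, gene, ffl_type).
#' @param edges Edge set the FFLs came from.
#' @return Named list of \code{\linkS4class{SubNetwork}}: \code{TF-SNW},
#'   \code{miRNA-SNW}, \code{composite-SNW}.
#' @export
buildSubnetworks <- function(ffls, edges) {
  out <- list()
  for (tp in .FFL_TYPES) {
    sub <- ffls[ffls$ffl_type == tp, , drop = FALSE]
    un <- .fflUnionEdges(sub, edges)
    nm <- sub("-FFL", "-SNW", tp)
    out[[nm]] <- new("SubNetwork", name = nm,
                     nodes = .nodeTable(un, .classOfNodes(un)),
                     edges = un, fflCount = nrow(sub))
  }
  out
}

#' Extract the hub-induced secondary sub-network
#'
#' Within each node class (gene, miRNA, TF) independently, ranks nodes
#' by degree and keeps the top \code{ceiling(quantile * n)} nodes,
#' including every node tied with the cutoff degree.  The secondary
#' sub-network is the subgraph induced on the kept nodes, with degrees
#' recomputed within it.
#'
#' @param snw A \code{\linkS4class{SubNetwork}}.
#' @param quantile Fraction of nodes to keep per class (default 0.25).
#' @return list(snw = the secondary \code{SubNetwork}, hubs = data.frame
#'   of the kept nodes with their degree in the parent network).
#' @export
extractHubs <- function(snw, quantile = 0.25) {
  nodes <- snwNodes(snw)
  hubs <- list()
  for (cl in c("gene", "miRNA", "TF")) {
    sub <- nodes[nodes$class == cl, , drop = FALSE]
    if (!nrow(sub)) {
      warning("no nodes of class ", cl, " in ", snwName(snw), "; skipped")
      next
    }
    kTop <- ceiling(quantile * nrow(sub))
    cutoff <- sort(sub$degree, decreasing = TRUE)[kTop]
    hubs[[cl]] <- sub[sub$degree >= cutoff, , drop = FALSE]
  }
  hubs <- do.call(rbind, hubs)
  rownames(hubs) <- NULL
  keepNodes <- hubs$node
  e <- snwEdges(snw)
  e <- e[e$source %in% keepNodes & e$target %in% keepNodes, , drop = FALSE]
  nt <- .nodeTable(e, stats::setNames(hubs$class, hubs$node))
  list(snw = new("SubNetwork", name = "secondary TF-SNW", nodes = nt,
                 edges = e, fflCount = fflCount(snw)),
       hubs = hubs)
}
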