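test_that("miRNA-target gates use strict thresholds and intersection", {
  tg <- data.frame(
    mirna = c("m1", "m2", "m3", "m4", "m5"),
    gene = c("g1", "g2", "g3", "g4", "g5"),
    context_score = c(-0.4, -0.31, -0.3, -0.5, NA),
    target_score = c(NA, 51, 80, 50, 90))
  got <- buildMirnaTargets(tg)
  ## only the pair passing both gates survives: cs -0.31 & ts 51
  expect_identical(got$source, "m2")
  ## cs = -0.3 exactly fails the strict "<"; ts = 50 fails ">"
  expect_false("m3" %in% got$source)
  expect_false("m4" %in% got$source)
  ## union keeps any pair passing either gate
  un <- buildMirnaTargets(tg, mode = "union")
  expect_setequal(un$source, c("m1", "m2", "m3", "m4", "m5"))
  ## TF-flagged targets are duplicated as miRNA-TF edges
  got2 <- buildMirnaTargets(tg, tfGenes = "g2")
  expect_setequal(got2$relation, c("miRNA-gene", "miRNA-TF"))
  expect_error(buildMirnaTargets(transform(tg, target_score = 200)),
               "malformed")
})

test_that("TF edge gates: core score exactly 1, matrix score strict", {
  sc <- data.frame(tf = c("t1", "t2", "t3", "t4"),
                   target = c("g1", "g2", "m1", "g3"),
                   target_class = c("gene", "gene", "mirna", "gene"),
                   matrix_score = c(0.96, 0.95, 0.99, 0.99),
                   core_score = c(1, 1, 1, 0.99))
  got <- buildTfEdges(sc)
  expect_setequal(got$source, c("t1", "t3"))
  expect_identical(got$relation[got$source == "t3"], "TF-miRNA")
  expect_error(buildTfEdges(transform(sc, target_class = "protein")),
               "unknown target_class")
})

test_that("the anti-correlation constraint drops same-direction and
           unannotated miRNA edges, with counts", {
  e <- data.frame(
    source = c("m1", "m1", "m2", "t1"),
    target = c("g1", "g2", "g3", "g1"),
    relation = c("miRNA-gene", "miRNA-gene", "miRNA-gene", "TF-gene"))
  res <- applyDirectionConstraint(
    e, mirnaDir = c(m1 = "up", m2 = "up"),
    targetDir = c(g1 = "down", g2 = "up"))
  expect_identical(nrow(res$edges), 2L)          # m1->g1 and the TF edge
  expect_identical(unname(res$dropped["same_direction"]), 1L)
  expect_identical(unname(res$dropped["unannotated"]), 1L)
  expect_true("TF-gene" %in% res$edges$relation) # TF edges unconstrained
})

test_that("FFL typing follows the exclusive edge rule", {
  base <- data.frame(source = c("t1", "t1", "m1"),
                     target = c("m1", "g1", "g1"),
                     relation = c("TF-miRNA", "TF-gene", "miRNA-gene"))
  one <- enumerateFFLs(base)
  expect_identical(one$ffls$ffl_type, "TF-FFL")
  ## adding the reciprocal miRNA-|TF edge flips it to composite
  comp <- enumerateFFLs(rbind(base, data.frame(
    source = "m1", target = "t1", relation = "miRNA-TF")))
  expect_identical(comp$ffls$ffl_type, "composite-FFL")
  ## miRNA-|TF alone gives a miRNA-FFL
  mir <- enumerateFFLs(base[-1, ] |> rbind(data.frame(
    source = "m1", target = "t1", relation = "miRNA-TF")))
  expect_identical(mir$ffls$ffl_type, "miRNA-FFL")
  expect_identical(nrow(enumerateFFLs(base[0, ])$ffls), 0L)
})

test_that("enumeration matches the brute-force triple scan", {
  for (seed in 1:8) {
    set.seed(seed)
    e <- randomEdgeSet(nTf = 4, nMir = 6, nGene = 8, nEdge = 70)
    fast <- enumerateFFLs(e)$ffls
    slow <- bruteForceFFLs(e)
    key <- function(d) sort(paste(d$tf, d$mirna, d$gene, d$ffl_type))
    expect_identical(key(fast), key(slow))
    ## every triple satisfies exactly one type predicate
    if (nrow(fast)) {
      has <- function(s, t, rel) paste(s, t, rel) %in%
        paste(e$source, e$target, e$relation)
      tm <- has(fast$tf, fast$mirna, "TF-miRNA")
      mt <- has(fast$mirna, fast$tf, "miRNA-TF")
      expect_true(all((fast$ffl_type == "composite-FFL") == (tm & mt)))
      expect_true(all((fast$ffl_type == "TF-FFL") == (tm & !mt)))
      expect_true(all((fast$ffl_type == "miRNA-FFL") == (!tm & mt)))
    }
  }
})

test_that("adding an edge never removes an existing FFL", {
  set.seed(21)
  e <- randomEdgeSet(nEdge = 50)
  before <- enumerateFFLs(e)$ffls
  extra <- data.frame(source = "tf01", target = "g01",
                      relation = "TF-gene")
  after <- enumerateFFLs(rbind(e, extra))$ffls
  key <- function(d) paste(d$tf, d$mirna, d$gene, d$ffl_type)
  expect_true(all(key(before) %in% key(after)))
})

test_that("summary accounting is internally consistent", {
  set.seed(3)
  e <- randomEdgeSet(nEdge = 90)
  s <- enumerateFFLs(e)$summary
  expect_identical(s$nodes$total, sum(unlist(s$nodes$by_class)))
  expect_identical(s$edges$total, sum(unlist(s$edges$by_relation)))
  expect_identical(s$ffl$total, sum(unlist(s$ffl$by_type)))
})

test_that("sub-networks carry consistent degrees and honest FFL counts", {
  set.seed(12)
  e <- randomEdgeSet(nEdge = 120)
  enum <- enumerateFFLs(e)
  snws <- buildSubnetworks(enum$ffls, e)
  expect_named(snws, c("TF-SNW", "miRNA-SNW", "composite-SNW"))
  tot <- sum(vapply(snws, fflCount, 0L))
  expect_identical(tot, nrow(enum$ffls))
  for (s in snws) expect_true(validObject(s))
})

test_that("hub extraction keeps ceil(25%) per class including ties", {
  mkSnw <- function(deg) {
    nodes <- data.frame(
      node = c(sprintf("g%d", seq_along(deg)), "m1", "m2", "m3", "m4",
               "t1", "t2", "t3", "t4"),
      class = c(rep("gene", length(deg)), rep("miRNA", 4), rep("TF", 4)),
      degree = c(deg, 4:1, 4:1))
    new("SubNetwork", name = "TF-SNW", nodes = nodes,
        edges = mirFFL:::.emptyEdges(), fflCount = 0L)
  }
  h1 <- extractHubs(mkSnw(c(5, 3, 2, 1)))$hubs
  expect_identical(h1$node[h1$class == "gene"], "g1")
  ## a tie at the cutoff keeps both tied nodes
  h2 <- extractHubs(mkSnw(c(5, 5, 2, 1)))$hubs
  expect_setequal(h2$node[h2$class == "gene"], c("g1", "g2"))
  ## independent rank-and-filter oracle on a random sub-network
  set.seed(8)
  e <- randomEdgeSet(nEdge = 150)
  snw <- buildSubnetworks(enumerateFFLs(e)$ffls, e)[["TF-SNW"]]
  got <- suppressWarnings(extractHubs(snw, 0.25))$hubs
  nodes <- snwNodes(snw)
  for (cl in unique(nodes$class)) {
    sub <- nodes[nodes$class == cl, ]
    cut <- sort(sub$degree, decreasing = TRUE)[ceiling(0.25 * nrow(sub))]
    expect_setequal(got$node[got$class == cl],
                    sub$node[sub$degree >= cut])
  }
})
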