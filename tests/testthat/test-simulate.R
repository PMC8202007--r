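test_that("seeded simulation is bit-reproducible", {
  cfg <- simConfig(nMirna = 60, nGene = 80, nTf = 20,
                   librarySizes = setNames(rep(2e5, 6), groupLabels()),
                   seed = 11)
  a <- simulateAll(cfg)
  b <- simulateAll(cfg)
  expect_identical(SummarizedExperiment::assay(a$counts, "counts"),
                   SummarizedExperiment::assay(b$counts, "counts"))
  expect_identical(a$targets, b$targets)
  expect_identical(a$tfbind, b$tfbind)
  expect_identical(as.data.frame(a$loci), as.data.frame(b$loci))
  expect_identical(a$ct, b$ct)
})

test_that("planted subtype ordering scales the group means exactly", {
  cfg <- simConfig(nMirna = 20, plantedPatterns = c(a1 = 3),
                   effectFold = 8, dispersion = 0.05, seed = 2,
                   librarySizes = setNames(rep(1e5, 6), groupLabels()))
  sim <- simulateCounts(cfg)
  mu <- sim$means
  planted <- unique(truePatterns(sim$truth)$mirna)
  for (m in planted) for (s in c("M", "F")) {
    expect_equal(mu[m, paste0(s, "T")], 8 * mu[m, paste0(s, "P")])
    expect_equal(mu[m, paste0(s, "P")], mu[m, paste0(s, "W")])
  }
  nonplanted <- setdiff(rownames(mu), planted)
  expect_true(all(apply(mu[nonplanted, ], 1,
                        function(r) diff(range(r)) == 0)))
})

test_that("no planted effect means an empty DEMIR answer key", {
  cfg <- simConfig(nMirna = 20, effectFold = 1, seed = 3,
                   plantedPatterns = c(a1 = 3, c1 = 2),
                   librarySizes = setNames(rep(1e5, 6), groupLabels()))
  sim <- simulateCounts(cfg)
  expect_identical(nrow(trueDemirs(sim$truth)), 0L)
  expect_true(all(truePatterns(sim$truth)$subtype == "flat"))
})

test_that("config validation rejects bad inputs", {
  expect_error(simConfig(librarySizes = setNames(c(0, rep(1e6, 5)),
                                                 groupLabels())),
               "positive")
  expect_error(simConfig(plantedPatterns = c(zz9 = 3)), "subtype")
  expect_error(simConfig(effectFold = 0.5), "effectFold")
  expect_error(simConfig(fracInRegion = 1.5), "frac")
})

test_that("locus placement hits the requested in-region count", {
  reg <- dlk1Dio3Region()
  mk <- function(n, frac, seed = 5)
    simConfig(nMirna = n, fracInRegion = frac, region = reg,
              plantedPatterns = c(a1 = 2), seed = seed)
  inRegion <- function(loci, reg) {
    m <- GenomicRanges::start(loci) +
      (GenomicRanges::width(loci) - 1L) %/% 2L
    sum(as.logical(GenomicRanges::seqnames(loci) ==
                     as.character(GenomicRanges::seqnames(reg))) &
          m >= GenomicRanges::start(reg) & m <= GenomicRanges::end(reg))
  }
  mir <- function(n) sprintf("miR-sim-%03d", seq_len(n))
  l0 <- simulateLoci(mk(50, 0), mir(50))
  expect_identical(inRegion(l0$loci, reg), 0L)
  expect_length(l0$inRegion, 0)
  l1 <- simulateLoci(mk(50, 1), mir(50))
  expect_identical(inRegion(l1$loci, reg), 50L)
  ## the published between-sex pool: 54 of 101 loci inside the cluster
  l54 <- simulateLoci(mk(101, 54 / 101), mir(101))
  expect_identical(inRegion(l54$loci, reg), 54L)
  expect_length(l54$inRegion, 54)
  tiny <- GenomicRanges::GRanges("chr12", IRanges::IRanges(10, 20))
  expect_error(simulateLoci(simConfig(nMirna = 5, fracInRegion = 1,
                                      plantedPatterns = c(a1 = 1),
                                      region = tiny, seed = 1), mir(5)),
               "too small")
})

test_that("planted edges pass the network thresholds and decoys fail", {
  cfg <- simConfig(nMirna = 60, nGene = 80, nTf = 20, seed = 7,
                   nPlantedFfl = c("TF-FFL" = 5, "miRNA-FFL" = 3,
                                   "composite-FFL" = 4),
                   nDecoy = 150)
  ed <- simulateEdges(cfg)
  truth <- trueFfls(ed$truth)
  expect_identical(nrow(truth), 12L)
  mg <- buildMirnaTargets(ed$targets,
                          tfGenes = ed$status$name[ed$status$is_tf])
  te <- buildTfEdges(ed$tfbind)
  enum <- enumerateFFLs(rbind(mg[c("source", "target", "relation")],
                              te[c("source", "target", "relation")]))
  key <- function(d) sort(paste(d$tf, d$mirna, d$gene, d$ffl_type))
  expect_identical(key(enum$ffls), key(truth))
})

test_that("zero planted loops yield zero downstream FFLs", {
  cfg <- simConfig(nMirna = 30, nGene = 40, nTf = 10, seed = 8,
                   plantedPatterns = c(a1 = 4),
                   nPlantedFfl = c("TF-FFL" = 0, "miRNA-FFL" = 0,
                                   "composite-FFL" = 0),
                   nDecoy = 100)
  ed <- simulateEdges(cfg)
  mg <- buildMirnaTargets(ed$targets,
                          tfGenes = ed$status$name[ed$status$is_tf])
  te <- buildTfEdges(ed$tfbind)
  enum <- enumerateFFLs(rbind(mg[c("source", "target", "relation")],
                              te[c("source", "target", "relation")]))
  expect_identical(nrow(enum$ffls), 0L)
})

test_that("a single planted composite loop is classified as composite", {
  cfg <- simConfig(nMirna = 30, nGene = 40, nTf = 10, seed = 9,
                   plantedPatterns = c(a1 = 4),
                   nPlantedFfl = c("TF-FFL" = 0, "miRNA-FFL" = 0,
                                   "composite-FFL" = 1),
                   nDecoy = 50)
  ed <- simulateEdges(cfg)
  mg <- buildMirnaTargets(ed$targets,
                          tfGenes = ed$status$name[ed$status$is_tf])
  te <- buildTfEdges(ed$tfbind)
  enum <- enumerateFFLs(rbind(mg[c("source", "target", "relation")],
                              te[c("source", "target", "relation")]))
  expect_identical(enum$ffls$ffl_type, "composite-FFL")
})

test_that("infeasible planting is rejected", {
  expect_error(simulateEdges(simConfig(nMirna = 30, nGene = 40, nTf = 2,
                                       plantedPatterns = c(a1 = 4),
                                       seed = 1)), "infeasible")
})

test_that("Ct values follow the abundance model", {
  cfg <- simConfig(nMirna = 10, seed = 4, plantedPatterns = c(a1 = 2),
                   librarySizes = setNames(rep(1e5, 6), groupLabels()))
  tpm <- matrix(c(2000, 1000, rep(1000, 10)), nrow = 2, ncol = 6,
                dimnames = list(c("mA", "mB"), groupLabels()))
  ct <- simulateCt(cfg, tpm = tpm, mirnas = c("mA", "mB"), noiseSd = 0)
  mw <- ct[ct$group == "MW", ]
  ## two-fold abundance ratio -> delta-Ct difference of exactly -1
  expect_equal(mw$ct[mw$mirna == "mA"] - mw$ct[mw$mirna == "mB"], -1)
  ## equal abundance -> delta-Ct 0 across groups for mB
  expect_equal(diff(range(ct$ct[ct$mirna == "mB"])), 0)
  ## ddct round-trips the fold change
  expect_equal(ddct(mw$ct[mw$mirna == "mA"], mw$ct[mw$mirna == "mB"]), 2)
  expect_identical(simulateCt(cfg, tpm = tpm), simulateCt(cfg, tpm = tpm))
})
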