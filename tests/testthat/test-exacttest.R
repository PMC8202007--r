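test_that("symmetric pairs give zero fold change and p = 1", {
  m <- matrix(c(120, 80, 120, 80), ncol = 2,
              dimnames = list(c("a", "b"), c("A", "B")))
  for (phi in c(0, 0.05)) {
    r <- exactTestPair(m, "A/B", dispersion = phi,
                       factors = c(A = 1, B = 1))
    expect_equal(r$log2fc, c(0, 0))
    expect_equal(r$pvalue, c(1, 1))
  }
})

test_that("the binomial closed form holds at phi = 0", {
  ## equal library totals, all 50 reads on one side:
  ## p = 2 x P(X >= 50 | Binom(50, 1/2)) = 2 x 2^-50
  m <- matrix(c(50, 0, 0, 50), ncol = 2,
              dimnames = list(c("a", "b"), c("A", "B")))
  r <- exactTestPair(m, "A/B", dispersion = 0, factors = c(A = 1, B = 1))
  expect_equal(r$pvalue[1], 2 * 2^-50)
  expect_equal(r$pvalue[2], 2 * 2^-50)
})

test_that("the NB kernel matches direct conditional-mass summation", {
  set.seed(42)
  for (i in 1:10) {
    xa <- rpois(1, exp(runif(1, 2, 7)))
    xb <- rpois(1, exp(runif(1, 2, 7)))
    na <- runif(1, 5e5, 2e6); nb <- runif(1, 5e5, 2e6)
    phi <- runif(1, 0.01, 0.2)
    got <- mirFFL:::.exactPvec(xa, xb, na, nb, phi)
    expect_equal(got, oracleExactP(xa, xb, na, nb, phi),
                 tolerance = 1e-10)
  }
  ## phi = 0 reduces to the binomial oracle as well
  expect_equal(mirFFL:::.exactPvec(30L, 4L, 1e6, 1.3e6, 0),
               oracleExactP(30, 4, 1e6, 1.3e6, 0), tolerance = 1e-12)
})

test_that("BH q-values match the step-up oracle and are monotone", {
  m <- toyCounts(60, depth = 3e5, seed = 5)
  r <- exactTestPair(m, "MT/MP", dispersion = 0.05)
  expect_equal(r$qvalue, bhStepUp(r$pvalue))
  o <- order(r$pvalue)
  expect_true(all(diff(r$qvalue[o]) >= -1e-12))
  ## permuting the row order changes nothing per miRNA
  perm <- sample(nrow(m))
  r2 <- exactTestPair(m[perm, ], "MT/MP", dispersion = 0.05)
  expect_equal(r2[match(r$mirna, r2$mirna), -1], r[, -1],
               ignore_attr = TRUE)
})

test_that("null p-values keep empirical type-I error near nominal", {
  ## no planted effect: 500 miRNAs, 20 seeded runs, all six contrasts
  hits <- 0; tests <- 0
  for (seed in 1:20) {
    cfg <- simConfig(nMirna = 500, effectFold = 1, dispersion = 0.05,
                     librarySizes = setNames(rep(1e6, 6), groupLabels()),
                     seed = seed)
    sim <- simulateCounts(cfg)
    rec <- runDE(sim$counts, dispersion = 0.05)
    hits <- hits + sum(rec$pvalue <= 0.05)
    tests <- tests + nrow(rec)
  }
  expect_lte(hits / tests, 0.07)
})

test_that("the DEMIR gate is inclusive at both boundaries", {
  expect_true(mirFFL:::.demirGate(0.05, 1))
  expect_false(mirFFL:::.demirGate(0.051, 1))
  expect_true(mirFFL:::.demirGate(0.01, -1))
  expect_false(mirFFL:::.demirGate(0.01, 0.999))
  r <- data.frame(mirna = c("a", "b"), contrast = "MT/MP",
                  log2fc = c(2, 0.5), pvalue = c(0.001, 0.5),
                  qvalue = c(0.01, 0.6),
                  significant = c(TRUE, FALSE),
                  direction = c("up", "none"))
  got <- callDemirs(r)
  expect_identical(got$demirs, "a")
  expect_identical(got$perContrast[["MT/MP"]], "a")
})

test_that("delta-delta-Ct closed forms hold", {
  expect_equal(ddct(25, 25), 1)
  expect_equal(ddct(24, 25), 2)
  expect_equal(ddct(28, 25), 0.125)
  expect_error(ddct(Inf, 25), "finite")
})

test_that("negative dispersion and unknown contrasts are rejected", {
  m <- toyCounts(10)
  expect_error(exactTestPair(m, "MT/MP", dispersion = -1), "dispersion")
  expect_error(exactTestPair(m, "MT/XX"), "unknown contrast")
})

test_that("QC: correlation, PCA and saturation behave as specified", {
  m <- toyCounts(40, depth = 1e5, seed = 2)
  m[, "FT"] <- m[, "MT"]  # duplicate library
  qc <- qcSummaries(m, seed = 3)
  expect_equal(qc$r2["MT", "FT"], 1)
  expect_false(qc$constant)
  sat <- qc$saturation
  full <- sat[sat$fraction == 1, ]
  expect_true(all(full$detected == colSums(m >= 1)[full$group]))
  ## nested thinning makes detection monotone in depth
  for (g in unique(sat$group)) {
    s <- sat[sat$group == g, ]
    expect_true(all(diff(s$detected[order(s$fraction)]) >= 0))
  }
  sat0 <- qcSummaries(m, depthFractions = c(0, 0.5), seed = 3)$saturation
  expect_true(all(sat0$detected[sat0$fraction == 0] == 0))
  ## constant table flagged, not crashed
  mc <- matrix(5L, 4, 6, dimnames = list(letters[1:4], groupLabels()))
  expect_true(qcSummaries(mc)$constant)
})
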