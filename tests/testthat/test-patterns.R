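test_that("worked grading examples map to the documented subtypes", {
  ## T/P up, T/W up, P/W ns  ->  T > P = W (a1, HCC-positive)
  a <- gradePatterns(relRecords(c(1, 1, 0)), "M")
  expect_equal(unlist(a[, c("grade_W", "grade_P", "grade_T")]),
               c(grade_W = 1, grade_P = 1, grade_T = 2))
  expect_identical(a$subtype, "a1")
  expect_identical(a$category, "HCC-positive")
  ## T/P ns, T/W up, P/W up  ->  W < P = T (b1, Ras-positive)
  b <- gradePatterns(relRecords(c(0, 1, 1)), "M")
  expect_identical(b$subtype, "b1")
  expect_identical(b$category, "Ras-positive")
  ## nothing significant -> flat, no category
  f <- gradePatterns(relRecords(c(0, 0, 0)), "M")
  expect_identical(f$subtype, "flat")
  expect_identical(f$category, "none")
  expect_identical(f$n_significant, 0L)
})

test_that("all 27 signed triples classify deterministically", {
  grid <- expand.grid(tp = -1:1, tw = -1:1, pw = -1:1)
  subtypes <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- gradePatterns(relRecords(unlist(grid[i, ]), sex = "F"), "F")
    subtypes[i] <- r$subtype
    ## grades exist iff consistent; min grade is always 1
    if (r$subtype != "inconsistent") {
      g <- unlist(r[, c("grade_W", "grade_P", "grade_T")])
      expect_equal(min(g), 1)
      expect_true(all(seq_len(max(g)) %in% g))
    }
  }
  expect_identical(sum(subtypes == "inconsistent"), 14L)
  named <- c("a1", "a2", "a3", "b1", "b2", "c1", "c2", "d1", "d2")
  expect_setequal(intersect(subtypes, named), named)
  expect_identical(sum(subtypes %in% named), 9L)
})

test_that("the 13 weak orders split into 9 named subtypes and 4 others", {
  orders <- mirFFL:::.weakOrders()
  expect_length(orders, 13)
  labels <- vapply(orders, subtypeOfGrades, character(1))
  named <- c("a1", "a2", "a3", "b1", "b2", "c1", "c2", "d1", "d2")
  expect_identical(sum(labels %in% named), 9L)
  expect_identical(sum(!labels %in% named), 4L)  # flat + 3 strict orders
  expect_identical(sum(labels == "flat"), 1L)
  expect_identical(sum(labels == "other"), 3L)
  ## subtype uniquely determines category
  expect_identical(categoryOfSubtype("a3"), "HCC-positive")
  expect_identical(categoryOfSubtype("d2"), "Ras-negative")
  expect_identical(categoryOfSubtype("other"), "none")
})

test_that("an inconsistent significance triple is labelled, not graded", {
  ## T>P, P>W, but T=W is contradictory
  r <- gradePatterns(relRecords(c(1, 0, 1)), "M")
  expect_identical(r$subtype, "inconsistent")
  expect_true(is.na(r$grade_W))
  expect_identical(r$category, "none")
})

test_that("the recurrence filter counts significant contrasts correctly", {
  mk <- function(mirna, relM, relF)
    rbind(gradePatterns(relRecords(relM, mirna, "M"), "M"),
          gradePatterns(relRecords(relF, mirna, "F"), "F"))
  one <- mk("m1", c(1, 0, 0), c(0, 0, 0))     # 1 significant total
  two <- mk("m2", c(1, 1, 0), c(0, 0, 0))     # 2 in one sex
  split <- mk("m3", c(1, 0, 0), c(1, 0, 0))   # 1 per sex
  all3 <- rbind(one, two, split)
  kept <- filterRecurrent(all3, minSig = 2, mode = "pooled")
  expect_setequal(unique(kept$mirna), c("m2", "m3"))
  keptPS <- filterRecurrent(all3, minSig = 2, mode = "per-sex")
  expect_setequal(unique(keptPS$mirna), "m2")
})

test_that("shared/unique calls recover a planted cross-sex fixture", {
  ## 79 shared (same category), 25 male-unique, 40 female-unique
  mk <- function(n, prefix, mSub, fSub) {
    ids <- sprintf("%s%03d", prefix, seq_len(n))
    rbind(data.frame(mirna = ids, sex = "M", grade_W = 1, grade_P = 1,
                     grade_T = 1, n_significant = 2L, subtype = mSub,
                     category = categoryOfSubtype(mSub)),
          data.frame(mirna = ids, sex = "F", grade_W = 1, grade_P = 1,
                     grade_T = 1, n_significant = 2L, subtype = fSub,
                     category = categoryOfSubtype(fSub)))
  }
  asg <- rbind(mk(68, "s", "c1", "c2"),   # shared, both HCC-negative
               mk(11, "t", "a1", "a2"),   # shared, both HCC-positive
               mk(25, "mu", "a1", "flat"),
               mk(40, "fu", "flat", "b2"))
  calls <- callSharedUnique(asg)
  expect_identical(sum(calls$status == "shared"), 79L)
  expect_identical(sum(calls$status == "male-unique"), 25L)
  expect_identical(sum(calls$status == "female-unique"), 40L)
  expect_identical(sum(calls$status == "discordant"), 0L)
  ## same subtype trivially shared; conflicting categories discordant
  d <- callSharedUnique(mk(1, "d", "a1", "c1"))
  expect_identical(d$status, "discordant")
})

test_that("category counts are invariant to miRNA order", {
  set.seed(1)
  cfg <- simConfig(nMirna = 80, seed = 5,
                   librarySizes = setNames(rep(3e5, 6), groupLabels()))
  rec <- runDE(simulateCounts(cfg)$counts, dispersion = 0.05)
  within <- rec[rec$contrast %in% withinSexContrasts("M"), ]
  a1 <- gradePatterns(within, "M")
  a2 <- gradePatterns(within[sample(nrow(within)), ], "M")
  expect_identical(table(a1$category), table(a2$category))
})

test_that("Venn counts partition each sex's significant sets", {
  cfg <- simConfig(nMirna = 60, seed = 6,
                   librarySizes = setNames(rep(3e5, 6), groupLabels()))
  rec <- runDE(simulateCounts(cfg)$counts, dispersion = 0.05)
  v <- vennCounts(rec)
  for (sex in c("M", "F")) {
    x <- v[[sex]]
    regions <- sum(x[c("only1", "only2", "only3", "int12", "int13",
                       "int23", "int123")])
    union <- length(unique(
      rec$mirna[rec$significant &
                  rec$contrast %in% withinSexContrasts(sex)]))
    expect_identical(unname(regions), union)
  }
})
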