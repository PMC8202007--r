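## Expression-pattern grading of the W/P/T trajectory, one sex at a time.
##
## Each significant within-sex contrast contributes a strict relation
## (numerator above/below denominator); non-significant contrasts an
## equality.  A consistent relation triple corresponds to exactly one of
## the 13 weak orders of {W, P, T}; grades start at 1 for the lowest
## level and increase by 1 per strict step.  Nine weak orders carry the
## named subtypes of the four categories; the all-equal order is "flat";
## the remaining three strict orders are "other"; contradictory triples
## are "inconsistent".

## grade triples (W, P, T) of the nine named subtypes
.SUBTYPE_GRADES <- list(
  a1 = c(1, 1, 2),  # T > P = W
  a2 = c(2, 1, 2),  # T = W > P
  a3 = c(2, 1, 3),  # T > W > P
  b1 = c(1, 2, 2),  # W < P = T
  b2 = c(1, 2, 3),  # W < P < T
  c1 = c(2, 2, 1),  # T < P = W
  c2 = c(1, 2, 1),  # T = W < P
  d1 = c(2, 1, 1),  # W > T = P
  d2 = c(3, 2, 1))  # W > P > T

.SUBTYPE_CATEGORY <- c(
  a1 = "HCC-positive", a2 = "HCC-positive", a3 = "HCC-positive",
  b1 = "Ras-positive", b2 = "Ras-positive",
  c1 = "HCC-negative", c2 = "HCC-negative",
  d1 = "Ras-negative", d2 = "Ras-negative",
  flat = "none", other = "none", inconsistent = "none")

## all 13 weak orders of {W,P,T} as grade triples (surjection onto a
## prefix of 1..3)
.weakOrders <- function() {
  out <- list()
  grid <- expand.grid(W = 1:3, P = 1:3, T = 1:3)
  for (i in seq_len(nrow(grid))) {
    g <- as.numeric(grid[i, ])
    if (min(g) == 1 && all(seq_len(max(g)) %in% g)) out[[length(out) + 1L]] <- g
  }
  out
}

#' Subtype of a (W, P, T) grade triple
#'
#' Maps a grade triple to its subtype label (\code{a1}..\code{d2},
#' \code{flat}, or \code{other}).
#'
#' @param grades Numeric length-3 vector of grades for (W, P, T).
#' @return Subtype label.
#' @export
#' @examples
#' subtypeOfGrades(c(1, 1, 2))  # T > P = W, subtype a1
subtypeOfGrades <- function(grades) {
  stopifnot(length(grades) == 3)
  for (s in names(.SUBTYPE_GRADES))
    if (all(grades == .SUBTYPE_GRADES[[s]])) return(s)
  if (all(grades == 1)) return("flat")
  "other"
}

#' Category of a subtype
#'
#' @param subtype Subtype label(s).
#' @return Category: \code{HCC-positive} (a), \code{Ras-positive} (b),
#'   \code{HCC-negative} (c), \code{Ras-negative} (d), or \code{none}.
#' @export
#' @examples
#' categoryOfSubtype(c("a1", "flat"))
categoryOfSubtype <- function(subtype) {
  unname(.SUBTYPE_CATEGORY[subtype])
}

## relation of contrast "X/Y": +1 X>Y, -1 X<Y, 0 X=Y
.relationOf <- function(significant, direction) {
  ifelse(!significant, 0L, ifelse(direction == "up", 1L, -1L))
}

#' Grade the W/P/T expression trajectory of each miRNA for one sex
#'
#' Consumes the three within-sex differential-expression contrasts
#' (\code{T/P}, \code{T/W}, \code{P/W}) and assigns each miRNA a grade
#' triple on \{W, P, T\} (1 = lowest level; +1 per significant step), the
#' subtype (\code{a1}..\code{d2}, \code{flat}, \code{other},
#' \code{inconsistent}) and the category.  A significant contrast orders
#' its two tissues by the sign of the fold change; a non-significant
#' contrast equates them.  Relation triples that admit no weak order
#' (e.g. T>W, W>P, T=P) are labelled \code{inconsistent}.
#'
#' @param records data.frame of differential-expression records (as from
#'   \code{\link{exactTestPair}}) restricted to one sex; must contain the
#'   three within-sex contrasts, with columns \code{mirna}, \code{contrast},
#'   \code{significant}, \code{direction}.
#' @param sex \code{"M"} or \code{"F"} (label only).
#' @return data.frame with one row per miRNA: \code{mirna}, \code{sex},
#'   \code{grade_W}, \code{grade_P}, \code{grade_T}, \code{n_significant},
#'   \code{subtype}, \code{category}.
#' @export
gradePatterns <- function(records, sex = c("M", "F")) {
  sex <- match.arg(sex)
  wanted <- withinSexContrasts(sex)
  records <- records[records$contrast %in% wanted, , drop = FALSE]
  if (!setequal(unique(records$contrast), wanted))
    stop("need exactly the three within-sex contrasts: ",
         paste(wanted, collapse = ", "))
  mirnas <- sort(unique(records$mirna))
  ## relation per contrast, rows = miRNAs
  rel <- matrix(0L, length(mirnas), 3, dimnames = list(mirnas, wanted))
  for (ct in wanted) {
    r <- records[records$contrast == ct, ]
    rel[match(r$mirna, mirnas), ct] <- .relationOf(r$significant, r$direction)
  }
  orders <- .weakOrders()
  ## relation triple implied by a grade triple g = (W,P,T) for contrasts
  ## (T/P, T/W, P/W)
  impliedRel <- t(vapply(orders, function(g)
    c(sign(g[3] - g[2]), sign(g[3] - g[1]), sign(g[2] - g[1])), numeric(3)))
  key <- apply(impliedRel, 1, paste, collapse = ",")
  obs <- apply(rel, 1, paste, collapse = ",")
  hit <- match(obs, key)
  grades <- t(vapply(seq_along(mirnas), function(i) {
    if (is.na(hit[i])) c(NA_real_, NA_real_, NA_real_) else orders[[hit[i]]]
  }, numeric(3)))
  subtype <- vapply(seq_along(mirnas), function(i) {
    if (is.na(hit[i])) "inconsistent" else subtypeOfGrades(orders[[hit[i]]])
  }, character(1))
  data.frame(
    mirna = mirnas, sex = sex,
    grade_W = grades[, 1], grade_P = grades[, 2], grade_T = grades[, 3],
    n_significant = as.integer(rowSums(rel != 0L)),
    subtype = subtype,
    category = categoryOfSubtype(subtype),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Keep miRNAs with recurrent significant changes
#'
#' Retains a miRNA when its significant within-sex pairwise contrasts
#' total at least \code{minSig}.  In \code{"pooled"} mode (default) the
#' six comparisons of both sexes are summed; in \code{"per-sex"} mode a
#' miRNA must reach \code{minSig} within a single sex.
#'
#' @param assignments Row-bound output of \code{\link{gradePatterns}} for
#'   both sexes.
#' @param minSig Minimum number of significant contrasts (default 2).
#' @param mode \code{"pooled"} or \code{"per-sex"}.
#' @return \code{assignments} restricted to the retained miRNAs.
#' @export
filterRecurrent <- function(assignments, minSig = 2L,
                            mode = c("pooled", "per-sex")) {
  mode <- match.arg(mode)
  tot <- tapply(assignments$n_significant, assignments$mirna,
                if (mode == "pooled") sum else max)
  keep <- names(tot)[tot >= minSig]
  assignments[assignments$mirna %in% keep, , drop = FALSE]
}

#' Shared/unique pattern calls between the sexes
#'
#' A miRNA is \emph{categorized} in a sex when its subtype belongs to one
#' of the four named categories (not flat/other/inconsistent).  Calls:
#' \code{shared} (same category in both sexes), \code{male-unique} /
#' \code{female-unique} (categorized in exactly one sex),
#' \code{discordant} (conflicting categories), \code{none} (categorized
#' in neither).
#'
#' @param assignments Row-bound \code{\link{gradePatterns}} output for
#'   both sexes.
#' @return data.frame(mirna, status, male_subtype, female_subtype,
#'   male_category, female_category).
#' @export
callSharedUnique <- function(assignments) {
  mirnas <- sort(unique(assignments$mirna))
  get <- function(sex, col) {
    a <- assignments[assignments$sex == sex, ]
    out <- a[[col]][match(mirnas, a$mirna)]
    ifelse(is.na(out), if (col == "category") "none" else "flat", out)
  }
  mSub <- get("M", "subtype"); fSub <- get("F", "subtype")
  mCat <- get("M", "category"); fCat <- get("F", "category")
  mOn <- mCat != "none"; fOn <- fCat != "none"
  status <- ifelse(mOn & fOn & mCat == fCat, "shared",
            ifelse(mOn & fOn, "discordant",
            ifelse(mOn, "male-unique",
            ifelse(fOn, "female-unique", "none"))))
  data.frame(mirna = mirnas, status = status,
             male_subtype = mSub, female_subtype = fSub,
             male_category = mCat, female_category = fCat,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-contrast Venn intersection counts of significant miRNAs
#'
#' For each sex, counts miRNAs significant in each of the three within-sex
#' contrasts and in every intersection of those contrast sets, mirroring
#' a three-set Venn diagram.
#'
#' @param records Differential-expression records for both sexes.
#' @return Named list per sex; each element a named integer vector of the
#'   7 Venn regions plus the per-contrast totals.
#' @export
vennCounts <- function(records) {
  out <- list()
  for (sex in .SEXES) {
    cts <- withinSexContrasts(sex)
    sets <- lapply(cts, function(ct)
      unique(records$mirna[records$contrast == ct & records$significant]))
    names(sets) <- cts
    inA <- sets[[1]]; inB <- sets[[2]]; inC <- sets[[3]]
    venn <- c(
      only1 = length(setdiff(inA, union(inB, inC))),
      only2 = length(setdiff(inB, union(inA, inC))),
      only3 = length(setdiff(inC, union(inA, inB))),
      int12 = length(setdiff(intersect(inA, inB), inC)),
      int13 = length(setdiff(intersect(inA, inC), inB)),
      int23 = length(setdiff(intersect(inB, inC), inA)),
      int123 = length(Reduce(intersect, sets)))
    tot <- vapply(sets, length, 0L)
    names(tot) <- paste0("total_", names(sets))
    out[[sex]] <- c(venn, tot)
  }
  out
}

#' Direction of a categorized miRNA in the tumor comparison
#'
#' Positive categories (HCC-/Ras-positive) correspond to up-regulation
#' towards tumor, negative categories to down-regulation; uncategorized
#' miRNAs get \code{NA}.  Used to feed the anti-correlation constraint of
#' the network stage.
#'
#' @param category Character vector of categories.
#' @return \code{"up"}, \code{"down"} or \code{NA}.
#' @export
#' @examples
#' directionOfCategory(c("HCC-positive", "Ras-negative", "none"))
directionOfCategory <- function(category) {
  ifelse(category %in% c("HCC-positive", "Ras-positive"), "up",
  ifelse(category %in% c("HCC-negative", "Ras-negative"), "down",
         NA_character_))
}
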