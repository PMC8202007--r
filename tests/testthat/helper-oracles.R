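# Independent oracles and fixture builders used across the suite.
# Every oracle is written from the definition, independently of the
# package's implementation path.

# brute-force O(n^3) feed-forward-loop scan over all node triples
bruteForceFFLs <- function(edges) {
  has <- function(s, t, rel)
    any(edges$source == s & edges$target == t & edges$relation == rel)
  tfs <- unique(c(edges$source[edges$relation %in% c("TF-gene", "TF-miRNA")],
                  edges$target[edges$relation == "miRNA-TF"]))
  mirs <- unique(c(edges$source[edges$relation %in%
                                  c("miRNA-gene", "miRNA-TF")],
                   edges$target[edges$relation == "TF-miRNA"]))
  genes <- unique(edges$target[edges$relation %in%
                                 c("TF-gene", "miRNA-gene")])
  out <- list()
  for (tf in tfs) for (m in mirs) for (g in genes) {
    if (tf == g) next
    if (!has(tf, g, "TF-gene") || !has(m, g, "miRNA-gene")) next
    tm <- has(tf, m, "TF-miRNA"); mt <- has(m, tf, "miRNA-TF")
    if (!tm && !mt) next
    type <- if (tm && mt) "composite-FFL" else if (tm) "TF-FFL"
            else "miRNA-FFL"
    out[[length(out) + 1L]] <- data.frame(
      tf = tf, mirna = m, gene = g, ffl_type = type,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(tf = character(), mirna = character(),
                      gene = character(), ffl_type = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# random typed edge set over nTf TFs, nMir miRNAs, nGene genes
randomEdgeSet <- function(nTf = 5, nMir = 10, nGene = 20, nEdge = 60) {
  tfs <- sprintf("tf%02d", seq_len(nTf))
  mirs <- sprintf("mir%02d", seq_len(nMir))
  genes <- sprintf("g%02d", seq_len(nGene))
  rel <- sample(c("TF-gene", "TF-miRNA", "miRNA-gene", "miRNA-TF"),
                nEdge, replace = TRUE)
  src <- ifelse(rel %in% c("TF-gene", "TF-miRNA"),
                sample(tfs, nEdge, TRUE), sample(mirs, nEdge, TRUE))
  tgt <- ifelse(rel == "TF-gene" | rel == "miRNA-gene",
                sample(genes, nEdge, TRUE),
                ifelse(rel == "TF-miRNA", sample(mirs, nEdge, TRUE),
                       sample(tfs, nEdge, TRUE)))
  e <- data.frame(source = src, target = tgt, relation = rel,
                  stringsAsFactors = FALSE)
  e[!duplicated(paste(e$source, e$target, e$relation)), ]
}

# conditional NB two-sided p by direct dnbinom summation over all
# splits of the total (definition-level oracle)
oracleExactP <- function(xa, xb, na, nb, phi) {
  n <- xa + xb
  if (n == 0) return(1)
  if (phi == 0) {
    p <- na / (na + nb)
    f <- dbinom(0:n, n, p)
  } else {
    r <- 1 / phi
    pihat <- n / (na + nb)
    f <- dnbinom(0:n, size = r, mu = pihat * na) *
      dnbinom(n - (0:n), size = r, mu = pihat * nb)
  }
  f <- f / sum(f)
  k <- 0:n
  min(1, 2 * min(sum(f[k <= xa]), sum(f[k >= xa])))
}

# manual Benjamini-Hochberg step-up
bhStepUp <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

# upper-tail hypergeometric p by direct enumeration
oracleHyperP <- function(count, termSize, uniSize, querySize) {
  j <- count:min(termSize, querySize)
  sum(choose(termSize, j) * choose(uniSize - termSize, querySize - j)) /
    choose(uniSize, querySize)
}

# minimal significant-record builder for pattern tests: rel is a named
# vector over the three within-sex contrasts with values 1 (up), -1
# (down), 0 (not significant)
relRecords <- function(rel, mirna = "miR-x", sex = "M") {
  cts <- withinSexContrasts(sex)
  stopifnot(length(rel) == 3)
  data.frame(mirna = mirna, contrast = cts,
             significant = rel != 0,
             direction = ifelse(rel == 0, "none",
                                ifelse(rel > 0, "up", "down")),
             stringsAsFactors = FALSE)
}

# small count fixture with named groups
toyCounts <- function(n = 20, depth = 5e4, seed = 1) {
  set.seed(seed)
  matrix(rpois(n * 6, depth / n), ncol = 6,
         dimnames = list(sprintf("miR-t%02d", seq_len(n)), groupLabels()))
}
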