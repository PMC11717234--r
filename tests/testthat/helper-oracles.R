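# Helpers and independent oracles used across the suite. Oracles are
# written naively (loops / enumeration / closed forms) and never share code
# with the implementation they check.

# GRanges from 0-based half-open coordinates, as used in the worked
# interval examples.
gr0 <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0),
                         ...)
}

# Brute-force O(F x E x G) oracle for the fragment filter: plain interval
# arithmetic on (chrom, start, end) triples, 1-based closed.
bruteFilterOracle <- function(m1, m2, repeats, genes) {
  asDf <- function(g) data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                                 start = BiocGenerics::start(g),
                                 end = BiocGenerics::end(g))
  d1 <- asDf(m1); d2 <- asDf(m2); re <- asDf(repeats); ge <- asDf(genes)
  containedIn <- function(m) {
    vapply(seq_len(nrow(m)), function(i) {
      any(re$chrom == m$chrom[i] & re$start <= m$start[i] & re$end >= m$end[i])
    }, logical(1))
  }
  overlapsGene <- function(m) {
    vapply(seq_len(nrow(m)), function(i) {
      any(ge$chrom == m$chrom[i] & ge$start <= m$end[i] & ge$end >= m$start[i])
    }, logical(1))
  }
  containedIn(d1) & containedIn(d2) & !overlapsGene(d1) & !overlapsGene(d2) &
    d1$chrom == d2$chrom
}

# Brute-force repName assignment oracle: unique repName over all containing
# elements of both mates, NA when ambiguous.
bruteAssignOracle <- function(m1, m2, repeats) {
  asDf <- function(g) data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                                 start = BiocGenerics::start(g),
                                 end = BiocGenerics::end(g))
  d1 <- asDf(m1); d2 <- asDf(m2)
  re <- asDf(repeats); re$repName <- repeats$repName
  vapply(seq_len(nrow(d1)), function(i) {
    names1 <- re$repName[re$chrom == d1$chrom[i] & re$start <= d1$start[i] &
                           re$end >= d1$end[i]]
    names2 <- re$repName[re$chrom == d2$chrom[i] & re$start <= d2$start[i] &
                           re$end >= d2$end[i]]
    u <- unique(c(names1, names2))
    if (length(u) == 1L) u else NA_character_
  }, character(1))
}

# Step-up BH by hand.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# GSEA running sum by literal accumulation (weight 1).
esOracle <- function(scores, members) {
  N <- length(scores)
  hit <- names(scores) %in% members
  nr <- sum(abs(scores)[hit])
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(scores[i]) / nr else -1 / (N - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (tie-free data).
wilcoxEnumOracle <- function(x, y) {
  all <- c(x, y)
  n <- length(x)
  r <- rank(all)
  wObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(all), n)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- mean(ws)
  p <- mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
  min(p, 1)
}

# Two-sided Fisher p by enumerating all tables at fixed margins.
fisherEnumOracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  prob <- function(a) dhyper(a, c1, n - c1, r1)
  pObs <- prob(tab[1, 1])
  as <- max(0, r1 + c1 - n):min(r1, c1)
  sum(vapply(as, prob, numeric(1))[vapply(as, prob, numeric(1)) <= pObs * (1 + 1e-7)])
}

# Upper-tail hypergeometric by summing binomial coefficients.
hyperEnumOracle <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

readTsvFile <- function(path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)

# Mean silhouette of a 1-d embedding under 2 known groups.
silhouette1d <- function(x, grp) {
  s <- vapply(seq_along(x), function(i) {
    own <- x[grp == grp[i]]; oth <- x[grp != grp[i]]
    a <- mean(abs(x[i] - own[-match(x[i], own)]))
    if (!is.finite(a)) a <- 0
    b <- mean(abs(x[i] - oth))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
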