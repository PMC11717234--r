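#' Rank features by signed significance
#'
#' Score = -log10(padj) x sign(log2FC), with padj floored at
#' \code{padjFloor} to keep scores finite. Features with NA padj are
#' dropped. Ties are broken deterministically: larger |log2FC| ranks more
#' extreme (toward its own end of the list), then feature id
#' lexicographically.
#'
#' @param res a \linkS4class{DEResult} or a data.frame with padj and
#'   log2FoldChange columns and feature rownames.
#' @param padjFloor floor applied before -log10; default 1e-300.
#' @return named numeric vector of scores, ordered from most positive to
#'   most negative.
#' @export
rankBySignedSignificance <- function(res, padjFloor = 1e-300) {
  r <- if (is(res, "DEResult")) as.data.frame(res@results) else res
  keep <- !is.na(r$padj) & !is.na(r$log2FoldChange)
  r <- r[keep, , drop = FALSE]
  score <- -log10(pmax(r$padj, padjFloor)) * sign(r$log2FoldChange)
  ord <- order(-score, -r$log2FoldChange, rownames(r))
  setNames(score[ord], rownames(r)[ord])
}

## Weighted Kolmogorov-Smirnov-like running sum: hit increments
## |score|^weight (normalized to sum 1 over hits), miss decrements
## 1/(N - Nh). ES is the signed maximum deviation.
gseaRunningSum <- function(scores, hitMask, weight = 1) {
  N <- length(scores)
  Nh <- sum(hitMask)
  inc <- abs(scores)^weight * hitMask
  tot <- sum(inc)
  if (tot == 0) inc[hitMask] <- 1 / Nh else inc <- inc / tot
  dec <- if (N > Nh) 1 / (N - Nh) else 0
  running <- cumsum(ifelse(hitMask, inc, -dec))
  i <- which.max(abs(running))
  list(es = running[i], at = i, running = running)
}

#' Gene set enrichment analysis by weighted running sum
#'
#' For each set, the enrichment score (ES) is the signed maximum deviation
#' of the running sum over the ranked list (hit steps weighted by
#' |score|^weight). The null is gene-label permutation: hit positions are
#' redrawn uniformly \code{nPerm} times. NES = ES / mean(|null ES| of
#' matching sign); the empirical p-value is two-sided on |ES| with +1
#' smoothing, BH-adjusted across sets. The gene ratio is the fraction of
#' set members in the leading edge.
#'
#' @param scores named numeric, ordered as produced by
#'   \code{\link{rankBySignedSignificance}}.
#' @param sets named list of feature-id vectors.
#' @param weight hit-weight exponent; default 1.
#' @param nPerm permutations; default 10000.
#' @param seed integer seed for the permutation null.
#' @param minSize,maxSize set-size bounds after intersection with the
#'   ranked list; defaults 10 and 500.
#' @return data.frame: set, size, ES, NES, pvalue, padj, geneRatio,
#'   leadingEdge (semicolon-separated). Sets with empty intersection or
#'   outside the size bounds are skipped with a note in the
#'   \code{skipped} attribute.
#' @export
runGSEA <- function(scores, sets, weight = 1, nPerm = 10000L, seed = 1L,
                    minSize = 10L, maxSize = 500L) {
  stopifnot(!is.null(names(scores)))
  N <- length(scores)
  skipped <- character(0)
  rows <- list()
  withr::with_seed(streamSeed(seed, "gsea-perm"), {
    for (nm in names(sets)) {
      members <- intersect(sets[[nm]], names(scores))
      if (length(members) == 0L) {
        skipped <- c(skipped, paste0(nm, ": no members in ranked list"))
        next
      }
      if (length(members) < minSize || length(members) > maxSize) {
        skipped <- c(skipped, paste0(nm, ": size ", length(members),
                                     " outside [", minSize, ",", maxSize, "]"))
        next
      }
      hit <- names(scores) %in% members
      obs <- gseaRunningSum(scores, hit, weight)
      Nh <- sum(hit)
      nullEs <- vapply(seq_len(nPerm), function(i) {
        hm <- logical(N)
        hm[sample.int(N, Nh)] <- TRUE
        gseaRunningSum(scores, hm, weight)$es
      }, numeric(1))
      sameSign <- nullEs[sign(nullEs) == sign(obs$es)]
      nes <- if (length(sameSign)) obs$es / mean(abs(sameSign)) else NA_real_
      p <- (1 + sum(abs(nullEs) >= abs(obs$es))) / (nPerm + 1)
      lead <- if (obs$es >= 0) names(scores)[seq_len(obs$at)][hit[seq_len(obs$at)]]
              else names(scores)[obs$at:N][hit[obs$at:N]]
      rows[[nm]] <- data.frame(
        set = nm, size = Nh, ES = obs$es, NES = nes, pvalue = p,
        geneRatio = length(lead) / Nh,
        leadingEdge = paste(lead, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), size = integer(0), ES = numeric(0),
               NES = numeric(0), pvalue = numeric(0), geneRatio = numeric(0),
               leadingEdge = character(0))
  out$padj <- bhAdjust(out$pvalue)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value of the overlap between the hit set and
#' each gene set, with the universe as margin; BH across sets. Gene ratio =
#' |hits in set| / |hits|.
#'
#' @param hits character vector of significant features (subset of
#'   universe).
#' @param universe all tested features.
#' @param sets named list of feature-id vectors.
#' @return data.frame: set, overlap, setSize, pvalue, padj, geneRatio.
#' @export
hypergeomORA <- function(hits, universe, sets) {
  if (length(universe) == 0L) stop("empty universe")
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  hits <- unique(hits)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(hits, s))
    p <- phyper(k - 1, length(s), length(universe) - length(s),
                length(hits), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, setSize = length(s), pvalue = p,
               geneRatio = if (length(hits)) k / length(hits) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bhAdjust(out$pvalue)
  rownames(out) <- NULL
  out
}

#' Blastocyst-stage expression value
#'
#' Per feature, the higher of the E3.5 inner-cell-mass and E3.5
#' trophectoderm TPM values — the single E3.5 summary used for the
#' developmental-trajectory plots.
#'
#' @param stageExpr matrix or data.frame, features x stages.
#' @param icmCol,teCol column names; defaults "E3.5_ICM", "E3.5_TE".
#' @return named numeric per feature.
#' @export
blastocystStageValue <- function(stageExpr, icmCol = "E3.5_ICM",
                                 teCol = "E3.5_TE") {
  miss <- setdiff(c(icmCol, teCol), colnames(stageExpr))
  if (length(miss)) stop("missing stage column(s): ",
                         paste(miss, collapse = ", "))
  setNames(pmax(stageExpr[, icmCol], stageExpr[, teCol]),
           rownames(stageExpr))
}

#' Weighted developmental log2 fold change
#'
#' 0.75 x (E3.5 trophectoderm vs 8-cell log2FC) + 0.25 x (E3.5 ICM vs
#' 8-cell log2FC), elementwise.
#'
#' @param lfcTeVs8c,lfcIcmVs8c finite numeric vectors.
#' @param wTe trophectoderm weight; default 0.75.
#' @return combined log2FC.
#' @export
weightedDevLog2FC <- function(lfcTeVs8c, lfcIcmVs8c, wTe = 0.75) {
  stopifnot(all(is.finite(lfcTeVs8c)), all(is.finite(lfcIcmVs8c)))
  wTe * lfcTeVs8c + (1 - wTe) * lfcIcmVs8c
}

#' Correlation between mutant deregulation and developmental change
#'
#' Pearson correlation between the mutant-vs-WT log2FC and the
#' developmental log2FC, reported both for the significant feature subset
#' and for all features.
#'
#' @param mutantLfc,devLfc paired finite numeric vectors (n >= 3).
#' @param significant logical vector marking the significant subset.
#' @return list: rAll, rSignificant (NA with a warning when a subset has
#'   zero variance or fewer than 3 members).
#' @export
delayCorrelation <- function(mutantLfc, devLfc, significant = NULL) {
  stopifnot(length(mutantLfc) == length(devLfc))
  if (length(mutantLfc) < 3L) stop("need at least 3 paired values")
  safeCor <- function(x, y) {
    if (length(x) < 3L) { warning("fewer than 3 values in subset"); return(NA_real_) }
    if (sd(x) == 0 || sd(y) == 0) { warning("zero variance"); return(NA_real_) }
    cor(x, y)
  }
  rAll <- safeCor(mutantLfc, devLfc)
  rSig <- if (is.null(significant)) NA_real_
          else safeCor(mutantLfc[significant], devLfc[significant])
  list(rAll = rAll, rSignificant = rSig)
}

#' Nonparametric bootstrap confidence interval for the mean
#'
#' Percentile interval of B resampled means (basic nonparametric
#' bootstrap); deterministic under the given seed.
#'
#' @param values numeric vector (n >= 2).
#' @param B bootstrap resamples; default 1000.
#' @param level confidence level; default 0.95.
#' @param seed integer seed.
#' @return named numeric: mean, lo, hi.
#' @export
bootstrapMeanCI <- function(values, B = 1000L, level = 0.95, seed = 1L) {
  if (length(values) < 2L) stop("need at least 2 values")
  withr::with_seed(streamSeed(seed, "bootstrap"), {
    means <- vapply(seq_len(B), function(i)
      mean(sample(values, replace = TRUE)), numeric(1))
    qs <- quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                   names = FALSE)
    c(mean = mean(values), lo = qs[1], hi = qs[2])
  })
}
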