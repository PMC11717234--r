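#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (restricted
#' to features with positive counts in every sample) of the ratio
#' count / geometric-mean-across-samples. Normalized counts are raw counts
#' divided by the size factor.
#'
#' @param counts matrix of non-negative counts, features x samples.
#' @return named positive numeric vector of size factors.
#' @examples
#' m <- cbind(s1 = c(10, 20), s2 = c(20, 40))
#' sizeFactorsMedianRatios(m)  # sqrt(1/2), sqrt(2)
#' @export
sizeFactorsMedianRatios <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L)
    return(setNames(1, colnames(counts)))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature has positive counts in all samples; ",
         "consider a pseudo-reference fallback")
  logGeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(cnt)
    exp(median(log(cnt) - logGeo)))
  setNames(sf, colnames(counts))
}

#' Normalized counts
#' @param counts count matrix.
#' @param sizeFactors optional precomputed size factors.
#' @return matrix of counts divided by size factors.
#' @export
normalizedCounts <- function(counts, sizeFactors = NULL) {
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatios(counts)
  sweep(as.matrix(counts), 2, sizeFactors, "/")
}

#' Transcripts per million
#'
#' rate = count / lengthKb; TPM = rate / sum(rate) x 10^6, per sample.
#'
#' @param counts matrix, features x samples (a vector is treated as one
#'   sample).
#' @param lengthKb per-feature lengths in kb (> 0).
#' @return TPM matrix; each sample column sums to 10^6 (all-zero samples
#'   stay zero, with a warning).
#' @export
computeTPM <- function(counts, lengthKb) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1)
  if (any(lengthKb <= 0)) stop("feature lengths must be > 0")
  rate <- sweep(as.matrix(counts), 1, lengthKb, "/")
  tot <- colSums(rate)
  if (any(tot == 0)) warning("all-zero sample(s); TPM left at zero")
  tot[tot == 0] <- 1
  sweep(rate, 2, tot, "/") * 1e6
}

#' Benjamini-Hochberg adjustment with NA propagation
#'
#' Step-up BH over the non-NA entries (the denominator is the number of
#' non-NA p-values); NA entries stay NA.
#'
#' @param p numeric vector of p-values in [0, 1] or NA.
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values outside [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  names(out) <- names(p)
  out
}

#' Independent filtering of low-information features
#'
#' Scans baseMean-quantile thresholds (default 0 to 95 percent in 1-percent
#' steps); for each threshold, BH is applied to the surviving features and
#' the threshold maximizing the number of rejections at \code{alpha} is
#' chosen (ties broken toward the lowest threshold). Features below the
#' chosen threshold get padj = NA and the filtered flag set.
#'
#' @param res a \linkS4class{DEResult}.
#' @param alpha significance cutoff used to optimize the filter; default
#'   0.05.
#' @param quantiles probabilities scanned; default seq(0, 0.95, 0.01).
#' @return the \linkS4class{DEResult} with refreshed padj and filter flags;
#'   attribute \code{filterThreshold} records the chosen baseMean cutoff.
#' @export
independentFiltering <- function(res, alpha = 0.05,
                                 quantiles = seq(0, 0.95, by = 0.01)) {
  stopifnot(is(res, "DEResult"))
  r <- res@results
  thr <- unname(quantile(r$baseMean, quantiles, na.rm = TRUE, type = 7))
  rejections <- vapply(thr, function(t) {
    use <- r$baseMean >= t & !is.na(r$pvalue)
    if (!any(use)) return(0L)
    sum(p.adjust(r$pvalue[use], "BH") < alpha)
  }, integer(1))
  best <- which.max(rejections)  # ties -> lowest threshold
  tBest <- thr[best]
  use <- r$baseMean >= tBest & !is.na(r$pvalue)
  r$padj <- NA_real_
  r$padj[use] <- p.adjust(r$pvalue[use], "BH")
  r$filtered <- r$baseMean < tBest
  out <- res
  out@results <- r
  attr(out, "filterThreshold") <- tBest
  attr(out, "filterQuantile") <- quantiles[best]
  validObject(out)
  out
}

#' Select negative-control genes across conditions
#'
#' A gene is a control iff in EVERY provided result: mean normalized count
#' (baseMean) > minMean, padj > minPadj, and |log2FC| < maxAbsLfc. The
#' fold-change criterion is read as an absolute value (a signed reading
#' would admit strongly downregulated genes, contradicting the purpose);
#' set \code{signed = TRUE} for the literal signed reading.
#'
#' @param resList list of \linkS4class{DEResult} (one per condition).
#' @param minMean,minPadj,maxAbsLfc thresholds; defaults 100, 0.8, 0.05.
#' @param signed use the signed log2FC reading; default FALSE.
#' @return character vector of control gene ids.
#' @export
selectControlGenes <- function(resList, minMean = 100, minPadj = 0.8,
                               maxAbsLfc = 0.05, signed = FALSE) {
  if (is(resList, "DEResult")) resList <- list(resList)
  if (length(resList) == 0L) stop("need at least one DEResult")
  ok <- NULL
  for (res in resList) {
    r <- res@results
    lfcOk <- if (signed) r$log2FoldChange < maxAbsLfc
             else abs(r$log2FoldChange) < maxAbsLfc
    pass <- !is.na(r$padj) & r$baseMean > minMean & r$padj > minPadj &
      !is.na(r$log2FoldChange) & lfcOk
    ids <- rownames(r)[pass]
    ok <- if (is.null(ok)) ids else intersect(ok, ids)
  }
  if (length(ok) == 0L)
    stop("no gene satisfies all control criteria in every condition; ",
         "consider relaxing minMean/minPadj/maxAbsLfc")
  ok
}

#' Factors of unwanted variation from control genes
#'
#' Centers log(normalized count + 1) of the control genes per gene, then
#' takes the first k singular-vector coordinates of the samples as the
#' unwanted-variation factors W (samples x k, orthogonal columns; each
#' column's sign is fixed so its largest-magnitude entry is positive).
#' Degenerate control matrices (constant across samples) yield all-zero W
#' with a warning.
#'
#' @param counts count matrix, features x samples.
#' @param controlIds control gene ids (subset of rownames).
#' @param k number of factors; default 6; must be < number of samples.
#' @param sizeFactors optional size factors.
#' @return a \linkS4class{RuvFactors}.
#' @export
ruvFactors <- function(counts, controlIds, k = 6L, sizeFactors = NULL) {
  counts <- as.matrix(counts)
  if (k >= ncol(counts)) stop("k must be smaller than the number of samples")
  missing <- setdiff(controlIds, rownames(counts))
  if (length(missing)) stop("control ids absent from counts: ",
                            paste(head(missing, 3), collapse = ", "))
  nc <- normalizedCounts(counts, sizeFactors)
  Y <- log(nc[controlIds, , drop = FALSE] + 1)
  Yc <- Y - rowMeans(Y)
  W <- matrix(0, ncol(counts), k,
              dimnames = list(colnames(counts), paste0("W", seq_len(k))))
  if (max(abs(Yc)) < 1e-12) {
    warning("control genes constant across samples; W is all zero")
  } else {
    sv <- svd(t(Yc), nu = k, nv = 0)
    kEff <- min(k, sum(sv$d > 1e-10 * sv$d[1]))
    if (kEff < k)
      warning("only ", kEff, " non-degenerate factor(s); remaining columns zero")
    if (kEff > 0) {
      U <- sv$u[, seq_len(kEff), drop = FALSE]
      for (j in seq_len(kEff)) {
        s <- sign(U[which.max(abs(U[, j])), j])
        if (s < 0) U[, j] <- -U[, j]
      }
      W[, seq_len(kEff)] <- U
    }
  }
  new("RuvFactors", W = W, controlGenes = as.character(controlIds))
}

#' PCA embedding of samples
#'
#' log2(normalized count + 1), removal of features with mean normalized
#' count <= minMean, selection of the top nTop features by variance, then
#' centered (unscaled) PCA of the samples.
#'
#' @param counts count matrix, features x samples.
#' @param nTop number of top-variance features; default 1000.
#' @param minMean mean normalized-count floor; default 10.
#' @param sizeFactors optional size factors.
#' @return list: \code{x} (sample coordinates), \code{varExplained}
#'   (fraction per component), \code{sdev}, \code{features} (ids used).
#' @export
pcaEmbed <- function(counts, nTop = 1000L, minMean = 10, sizeFactors = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  nc <- normalizedCounts(counts, sizeFactors)
  keep <- rowMeans(nc) > minMean
  if (!any(keep)) stop("no feature passes the mean filter")
  lg <- log2(nc[keep, , drop = FALSE] + 1)
  v <- matrixStats::rowVars(lg)
  if (sum(keep) < nTop) {
    warning("only ", sum(keep), " features pass the filter; using all")
    nTop <- sum(keep)
  }
  top <- order(v, decreasing = TRUE)[seq_len(nTop)]
  pc <- prcomp(t(lg[top, , drop = FALSE]), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(x = pc$x, varExplained = ve, sdev = pc$sdev,
       features = rownames(lg)[top])
}
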