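#' Assign sex from Y-linked gene expression
#'
#' Sums size-factor-normalized counts over the Y-linked genes per embryo and
#' calls male when the score exceeds the threshold, female when it is at or
#' below it (ties go to female). Scores within \code{ambiguityBand} of the
#' threshold are called ambiguous. A simple bimodality diagnostic is
#' attached: the largest gap between consecutive sorted scores relative to
#' the score range (flagging a single cluster when the scores do not split).
#'
#' @param normCounts matrix of normalized counts, genes x samples.
#' @param yGenes Y-linked gene ids (must be rows of normCounts).
#' @param threshold score cutoff; default 10 normalized counts.
#' @param ambiguityBand half-width of the ambiguous zone; default 0.
#' @return data.frame with sample, score, sexCall; attribute
#'   \code{diagnostic} (list: gap, gapFraction, singleCluster).
#' @export
assignSex <- function(normCounts, yGenes, threshold = 10,
                      ambiguityBand = 0) {
  missing <- setdiff(yGenes, rownames(normCounts))
  if (length(missing))
    stop("Y-linked gene(s) not in matrix: ", paste(missing, collapse = ", "))
  score <- colSums(normCounts[yGenes, , drop = FALSE])
  call <- ifelse(score > threshold, "male", "female")
  if (ambiguityBand > 0)
    call[abs(score - threshold) <= ambiguityBand] <- "ambiguous"
  s <- sort(score)
  rng <- diff(range(s))
  gap <- if (length(s) > 1) max(diff(s)) else 0
  diag. <- list(gap = gap,
                gapFraction = if (rng > 0) gap / rng else 0,
                singleCluster = rng == 0 || gap / max(rng, 1e-12) < 0.5)
  out <- data.frame(sample = colnames(normCounts), score = as.numeric(score),
                    sexCall = call, stringsAsFactors = FALSE)
  attr(out, "diagnostic") <- diag.
  out
}

#' Call the allele at the mutated codon from locus-spanning reads
#'
#' Classifies each read by exact substring matching against the WT,
#' missense and deletion templates over the codon window: a read counts for
#' the unique template it is consistent with (reads consistent with more
#' than one template, e.g. too short to span the codon, are ignored).
#' Deletion consistency works on the full read sequence including any
#' soft-clipped tail, so reads whose aligned prefix matches WT up to the
#' codon and whose clipped tail matches the post-deletion junction are
#' recognized without deletion-aware alignment records. The call is the
#' single allele with at least \code{minReads} supporting reads;
#' heterozygous when two alleles each reach \code{minReads} and each holds
#' at least \code{hetMinFraction} of informative reads; no-call below
#' \code{minReads}. A WT call with zero mutant-supporting reads carries the
#' \code{wtByAbsence} qualifier: it rests only on the absence of mutant
#' reads.
#'
#' @param reads character vector of read sequences over the codon window
#'   (soft-clipped bases included), or a data.frame with a \code{seq}
#'   column as returned by \code{\link{readLocusReadsSam}}.
#' @param templates named character vector with entries WT, missense,
#'   deletion (see \code{\link{alleleTemplates}}); must be pairwise
#'   distinguishing.
#' @param minReads minimum informative reads per supported allele; default 3.
#' @param hetMinFraction minimum fraction per allele for a heterozygous
#'   call; default 0.2.
#' @return list: call, nWT, nMissense, nDeletion, nInformative,
#'   wtByAbsence.
#' @export
callAlleleAtLocus <- function(reads, templates, minReads = 3L,
                              hetMinFraction = 0.2) {
  if (is.data.frame(reads)) reads <- reads$seq
  need <- c("WT", "missense", "deletion")
  if (!all(need %in% names(templates)))
    stop("templates must be named WT, missense, deletion")
  templates <- templates[need]
  for (i in 1:2) for (j in (i + 1):3)
    if (grepl(templates[i], templates[j], fixed = TRUE) ||
        grepl(templates[j], templates[i], fixed = TRUE))
      stop("templates do not distinguish alleles: ", need[i], " vs ", need[j])

  consistent <- vapply(reads, function(r) {
    vapply(templates, function(t)
      grepl(r, t, fixed = TRUE) || grepl(t, r, fixed = TRUE), logical(1))
  }, logical(3))
  if (length(reads) == 0L)
    consistent <- matrix(FALSE, nrow = 3,
                         dimnames = list(need, NULL))
  informative <- colSums(consistent) == 1L
  hits <- consistent[, informative, drop = FALSE]
  n <- setNames(rowSums(hits), need)
  nInf <- sum(n)

  supported <- names(n)[n >= minReads]
  call <- if (nInf < minReads || length(supported) == 0L) {
    "no-call"
  } else if (length(supported) >= 2L) {
    top2 <- names(sort(n[supported], decreasing = TRUE))[1:2]
    if (all(n[top2] / nInf >= hetMinFraction)) "heterozygous"
    else names(which.max(n))
  } else supported
  list(call = call, nWT = unname(n["WT"]), nMissense = unname(n["missense"]),
       nDeletion = unname(n["deletion"]), nInformative = nInf,
       wtByAbsence = call == "WT" && (n["missense"] + n["deletion"]) == 0)
}

#' Genotype from degron-tag-mapping read counts
#'
#' A sample is wild type iff the sum of tag-mapping reads is strictly below
#' the cutoff (default 72), otherwise tagged. A step function with a single
#' transition at the cutoff.
#'
#' @param tagReadSum non-negative integer vector.
#' @param cutoff default 72.
#' @return character vector, "WT" or "tagged".
#' @export
genotypeFromTagCounts <- function(tagReadSum, cutoff = 72L) {
  if (any(tagReadSum < 0)) stop("tag read counts must be >= 0")
  ifelse(tagReadSum < cutoff, "WT", "tagged")
}

#' Quality-control filter for single-embryo libraries
#'
#' Discards embryos with fewer than \code{depthMin} total reads, then flags
#' robust outliers on either the mitochondrial-fraction or rDNA-fraction
#' axis: |x - median(x)| > madK x MAD(x), with medians and MADs computed on
#' the depth-passing embryos. A zero MAD on an axis means no outliers on
#' that axis. With fewer than 4 depth-passing embryos the outlier step is
#' skipped with a warning. Deterministic, permutation-invariant, and
#' idempotent on its kept set.
#'
#' @param records data.frame with columns sample, totalReads, mtFraction,
#'   rdnaFraction.
#' @param depthMin minimum total reads; default 1e6.
#' @param madK outlier multiplier; default 3.
#' @return list: \code{kept} (data.frame) and \code{discarded} (data.frame
#'   with a \code{reasons} column; semicolon-separated reason codes among
#'   depth, mt-outlier, rdna-outlier).
#' @export
qcFilterEmbryos <- function(records, depthMin = 1e6, madK = 3) {
  stopifnot(all(c("sample", "totalReads", "mtFraction", "rdnaFraction") %in%
                  colnames(records)))
  reasons <- setNames(vector("list", nrow(records)), records$sample)
  deep <- records$totalReads >= depthMin
  for (i in which(!deep)) reasons[[i]] <- c(reasons[[i]], "depth")

  if (sum(deep) < 4L) {
    if (sum(deep) > 0L)
      warning("fewer than 4 depth-passing embryos; outlier step skipped")
  } else {
    for (ax in c("mtFraction", "rdnaFraction")) {
      x <- records[[ax]][deep]
      md <- median(x)
      mv <- mad(x)
      if (mv > 0) {
        out <- abs(records[[ax]] - md) > madK * mv & deep
        code <- if (ax == "mtFraction") "mt-outlier" else "rdna-outlier"
        for (i in which(out)) reasons[[i]] <- c(reasons[[i]], code)
      }
    }
  }
  bad <- lengths(reasons) > 0L
  discarded <- records[bad, , drop = FALSE]
  discarded$reasons <- vapply(reasons[bad], paste, character(1),
                              collapse = ";")
  list(kept = records[!bad, , drop = FALSE], discarded = discarded)
}
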