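#' Filter paired-end fragments for repeat quantification
#'
#' Keeps a fragment if and only if BOTH mates are each fully contained
#' within a single repeat element AND NEITHER mate overlaps any gene body by
#' one or more bp. Containment is evaluated per mate against single
#' elements: a mate spanning two abutting elements (even of the same
#' repName) is not contained. Overlap with genes is unstranded. The filter
#' preserves input order and is idempotent.
#'
#' @param fragments a \linkS4class{PairedFragments}.
#' @param repeats GRanges of repeat elements.
#' @param genes GRanges of gene bodies.
#' @return the kept \linkS4class{PairedFragments} (possibly empty).
#' @export
filterRepeatFragments <- function(fragments, repeats, genes) {
  if (length(fragments) == 0L) return(fragments)
  m1 <- firstMate(fragments)
  m2 <- secondMate(fragments)
  within1 <- IRanges::overlapsAny(m1, repeats, type = "within",
                                  ignore.strand = TRUE)
  within2 <- IRanges::overlapsAny(m2, repeats, type = "within",
                                  ignore.strand = TRUE)
  geneHit1 <- IRanges::overlapsAny(m1, genes, ignore.strand = TRUE)
  geneHit2 <- IRanges::overlapsAny(m2, genes, ignore.strand = TRUE)
  sameChrom <- as.character(GenomicRanges::seqnames(m1)) ==
    as.character(GenomicRanges::seqnames(m2))
  keep <- within1 & within2 & !geneHit1 & !geneHit2 & sameChrom
  PairedFragments(m1[keep], m2[keep])
}

#' Count filtered fragments per repName
#'
#' Fragment-level, unstranded counting: a fragment is assigned to repName R
#' iff both mates are fully contained in elements whose repName is R.
#' Fragments whose mates fall in elements of different repNames are
#' discarded as ambiguous (and counted in the table's metadata). The
#' summarized length of a repName is the sum of its element lengths.
#'
#' @param fragments \linkS4class{PairedFragments} that already passed
#'   \code{\link{filterRepeatFragments}}.
#' @param repeats GRanges of repeat elements with
#'   repName/repFamily/repClass.
#' @param inputReads aligner input read count for the sample (reads, not
#'   fragments).
#' @param sampleName sample label.
#' @return a \linkS4class{RepeatCountTable} with one sample column.
#' @export
countByRepName <- function(fragments, repeats, inputReads,
                           sampleName = "s1") {
  repNames <- sort(unique(repeats$repName))
  lengthKb <- vapply(repNames, function(r)
    sum(GenomicRanges::width(repeats)[repeats$repName == r]) / 1000,
    numeric(1))
  counts <- matrix(0L, nrow = length(repNames), ncol = 1L,
                   dimnames = list(repNames, sampleName))
  nAmb <- 0L
  if (length(fragments) > 0L) {
    m1 <- firstMate(fragments)
    m2 <- secondMate(fragments)
    h1 <- GenomicRanges::findOverlaps(m1, repeats, type = "within",
                                      ignore.strand = TRUE)
    h2 <- GenomicRanges::findOverlaps(m2, repeats, type = "within",
                                      ignore.strand = TRUE)
    if (length(unique(S4Vectors::queryHits(h1))) < length(fragments) ||
        length(unique(S4Vectors::queryHits(h2))) < length(fragments))
      stop("internal error: fragment without containing element; ",
           "run filterRepeatFragments first")
    name1 <- split(repeats$repName[S4Vectors::subjectHits(h1)],
                   S4Vectors::queryHits(h1))
    name2 <- split(repeats$repName[S4Vectors::subjectHits(h2)],
                   S4Vectors::queryHits(h2))
    assigned <- vapply(seq_len(length(fragments)), function(i) {
      u <- unique(c(name1[[as.character(i)]], name2[[as.character(i)]]))
      if (length(u) == 1L) u else NA_character_
    }, character(1))
    nAmb <- sum(is.na(assigned))
    tab <- table(factor(assigned[!is.na(assigned)], levels = repNames))
    counts[, 1L] <- as.integer(tab)
  }
  new("RepeatCountTable", counts = counts, lengthKb = lengthKb,
      inputReads = setNames(as.numeric(inputReads), sampleName),
      nameToFamily = setNames(repeats$repFamily,
                              repeats$repName)[repNames],
      nameToClass = setNames(repeats$repClass, repeats$repName)[repNames],
      ambiguousFragments = setNames(as.numeric(nAmb), sampleName))
}

#' Combine single-sample RepeatCountTables into one multi-sample table
#' @param ... RepeatCountTable objects sharing the same repNames.
#' @return a multi-sample \linkS4class{RepeatCountTable}.
#' @export
bindRepeatCounts <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is(tabs[[1]], "RepeatCountTable"))
    tabs <- tabs[[1]]
  ref <- tabs[[1]]
  for (t in tabs[-1])
    if (!identical(rownames(t@counts), rownames(ref@counts)))
      stop("repNames differ between tables")
  new("RepeatCountTable",
      counts = do.call(cbind, lapply(tabs, slot, "counts")),
      lengthKb = ref@lengthKb,
      inputReads = do.call(c, lapply(tabs, slot, "inputReads")),
      nameToFamily = ref@nameToFamily, nameToClass = ref@nameToClass,
      ambiguousFragments = do.call(c, lapply(tabs, slot,
                                             "ambiguousFragments")))
}

## core FPKM formula: count / (inputReads / 2) * 1e6 / lengthKb.
## inputReads are aligner input *reads*; the /2 converts to fragments to
## match fragment-level counting.
.fpkm <- function(counts, inputReads, lengthKb) {
  if (any(inputReads <= 0)) stop("input read count must be > 0")
  perM <- sweep(counts, 2, inputReads / 2, "/") * 1e6
  sweep(perM, 1, lengthKb, "/")
}

#' FPKM at the repName level
#'
#' FPKM(r, s) = [count(r, s) / (inputReads(s) / 2) x 10^6] / lengthKb(r),
#' with inputReads the aligner input read count and lengthKb the summarized
#' length of the repName.
#'
#' @param table a \linkS4class{RepeatCountTable}.
#' @return an \linkS4class{FpkmTable} at level "repName".
#' @export
fpkmByRepName <- function(table) {
  counted <- rowSums(table@counts) > 0
  if (any(table@lengthKb[counted] <= 0))
    stop("summarized length must be > 0 for counted repNames")
  new("FpkmTable", level = "repName",
      fpkm = .fpkm(table@counts, table@inputReads, table@lengthKb),
      dnaFpkm = numeric(0), featureClass = table@nameToClass)
}

#' FPKM at the repFamily level
#'
#' Family FPKM = [sum of member counts / (inputReads / 2) x 10^6] / sum of
#' member summarized lengths (kb): the count-weighted aggregation, not the
#' mean of member FPKMs.
#'
#' @param table a \linkS4class{RepeatCountTable}.
#' @return an \linkS4class{FpkmTable} at level "repFamily".
#' @export
fpkmByRepFamily <- function(table) {
  fam <- table@nameToFamily[rownames(table@counts)]
  famCounts <- rowsum(table@counts, fam)
  famLen <- rowsum(table@lengthKb, fam)[, 1]
  famLen <- famLen[rownames(famCounts)]
  famClass <- vapply(rownames(famCounts), function(f)
    unique(table@nameToClass[names(fam)[fam == f]])[1], character(1))
  new("FpkmTable", level = "repFamily",
      fpkm = .fpkm(famCounts, table@inputReads, famLen),
      dnaFpkm = numeric(0), featureClass = famClass)
}

#' DNA-contamination covariate from repName-level FPKM
#'
#' Sums FPKM over DNA-class repNames per sample — the confounding covariate
#' added to the repeat differential-expression design — and flags samples
#' whose value exceeds a robust outlier bound (median + madK x MAD across
#' samples), the reproducible stand-in for a visual check of DNA-transposon
#' FPKM.
#'
#' @param fpkm an \linkS4class{FpkmTable} at level "repName".
#' @param madK robust-outlier multiplier; default 3.
#' @return the input FpkmTable with \code{dnaFpkm} filled, plus attributes
#'   accessible via \code{\link{dnaFpkm}} and the \code{flagged} attribute
#'   (named logical per sample).
#' @export
dnaContamination <- function(fpkm, madK = 3) {
  stopifnot(is(fpkm, "FpkmTable"))
  isDna <- fpkm@featureClass[rownames(fpkm@fpkm)] == "DNA"
  if (!any(isDna)) {
    warning("no DNA-class features in annotation; covariate is all zero")
    v <- setNames(numeric(ncol(fpkm@fpkm)), colnames(fpkm@fpkm))
  } else {
    v <- colSums(fpkm@fpkm[isDna, , drop = FALSE])
  }
  md <- median(v)
  mv <- mad(v)
  flagged <- if (mv == 0) setNames(rep(FALSE, length(v)), names(v))
             else v > md + madK * mv
  out <- fpkm
  out@dnaFpkm <- v
  attr(out, "flagged") <- flagged
  out
}

#' Write repeat count and FPKM tables with a sidecar YAML
#'
#' @param table a \linkS4class{RepeatCountTable}.
#' @param fpkm an \linkS4class{FpkmTable} (optional).
#' @param prefix output path prefix; writes \code{<prefix>_counts.tsv},
#'   optionally \code{<prefix>_fpkm.tsv}, and \code{<prefix>.yaml} recording
#'   depths and contamination flags.
#' @export
writeRepeatTables <- function(table, fpkm = NULL, prefix) {
  writeCountsTsv(table@counts, paste0(prefix, "_counts.tsv"))
  side <- list(inputReads = as.list(table@inputReads),
               ambiguousFragments = as.list(table@ambiguousFragments))
  if (!is.null(fpkm)) {
    writeCountsTsv(round(fpkm@fpkm, 6), paste0(prefix, "_fpkm.tsv"))
    if (length(fpkm@dnaFpkm)) side$dnaFpkm <- as.list(round(fpkm@dnaFpkm, 6))
    fl <- attr(fpkm, "flagged")
    if (!is.null(fl)) side$flaggedSamples <- as.list(fl)
  }
  yaml::write_yaml(side, paste0(prefix, ".yaml"))
  invisible(prefix)
}
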