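#' Simulation configuration for the synthetic study generator
#'
#' Holds every knob of the synthetic-data generators: the toy genome and
#' annotation geometry, the negative-binomial count model, library depth,
#' DNA-contamination fractions, batch strength and the per-sample mixture of
#' alleles at the mutated codon. Identical configurations (including
#' \code{seed}) produce byte-identical outputs.
#'
#' @slot seed master seed; every generator derives its own stream from it.
#' @slot nChromosomes number of autosome-like chromosomes (chrY and chrM are
#'   always appended).
#' @slot chromLengthBp length of each autosome-like chromosome in bp.
#' @slot nRepeatElements total number of repeat element copies to place.
#' @slot repnameCatalog data.frame with columns repName, repFamily, repClass;
#'   must include at least one DNA-class entry.
#' @slot nGenes number of autosomal single-copy genes (Y-linked,
#'   mitochondrial and an rDNA-proxy gene are added on top).
#' @slot nSamplesPerGroup samples per biological group.
#' @slot meanDepthFragments expected sequenced fragments per sample.
#' @slot nbDispersion negative-binomial dispersion alpha (> 0), so that
#'   Var = mu + alpha * mu^2.
#' @slot effectLog2FC named numeric: true log2 fold change per perturbed
#'   feature (unnamed features are null).
#' @slot dnaContaminationFraction per-sample fraction of fragments that are
#'   genomic-DNA contaminants (recycled across samples), in [0, 1].
#' @slot batchStrength standard-deviation (in log2 units) of the per-sample
#'   batch term; 0 disables batch structure.
#' @slot alleleMix numeric matrix (samples x 3, columns wt/missense/deletion)
#'   of allele fractions at the mutated codon; rows sum to 1. May have 0 rows
#'   when no allele structure is simulated.
#'
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nChromosomes = "integer",
  chromLengthBp = "integer",
  nRepeatElements = "integer",
  repnameCatalog = "data.frame",
  nGenes = "integer",
  nSamplesPerGroup = "integer",
  meanDepthFragments = "integer",
  nbDispersion = "numeric",
  effectLog2FC = "numeric",
  dnaContaminationFraction = "numeric",
  batchStrength = "numeric",
  alleleMix = "matrix"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  cat. <- object@repnameCatalog
  if (!all(c("repName", "repFamily", "repClass") %in% colnames(cat.)))
    msg <- c(msg, "repnameCatalog needs repName/repFamily/repClass columns")
  if (nrow(cat.) == 0L) msg <- c(msg, "repnameCatalog is empty")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
  f <- object@dnaContaminationFraction
  if (any(f < 0 | f > 1)) msg <- c(msg, "dnaContaminationFraction outside [0,1]")
  if (any(object@batchStrength < 0)) msg <- c(msg, "batchStrength must be >= 0")
  am <- object@alleleMix
  if (nrow(am) > 0L) {
    if (ncol(am) != 3L) msg <- c(msg, "alleleMix needs 3 columns (wt/missense/deletion)")
    else {
      if (any(am < 0 | am > 1)) msg <- c(msg, "allele fractions outside [0,1]")
      if (any(abs(rowSums(am) - 1) > 1e-8)) msg <- c(msg, "allele fractions must sum to 1 per sample")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults encode the synthetic study conditions used throughout the
#' package: two-group single-embryo cohorts of 10 samples per group, a
#' repeat catalog spanning LTR/LINE/SINE plus DNA transposons and
#' simple/low-complexity entries, moderate biological dispersion (0.05) and
#' a small genomic-DNA contamination fraction (0.05). See the methods
#' vignette for the rationale behind each default.
#'
#' @param seed integer master seed.
#' @param nChromosomes,chromLengthBp,nRepeatElements,nGenes annotation
#'   geometry.
#' @param repnameCatalog repeat catalog (repName/repFamily/repClass).
#' @param nSamplesPerGroup,meanDepthFragments,nbDispersion count model.
#' @param effectLog2FC named numeric of true effects; default none (null).
#' @param dnaContaminationFraction,batchStrength,alleleMix see class slots.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- SimConfig(seed = 1, nGenes = 20)
#' @export
SimConfig <- function(seed = 1L,
                      nChromosomes = 2L,
                      chromLengthBp = 400000L,
                      nRepeatElements = 60L,
                      repnameCatalog = defaultRepeatCatalog(),
                      nGenes = 60L,
                      nSamplesPerGroup = 10L,
                      meanDepthFragments = 20000L,
                      nbDispersion = 0.05,
                      effectLog2FC = numeric(0),
                      dnaContaminationFraction = 0.05,
                      batchStrength = 0,
                      alleleMix = matrix(numeric(0), nrow = 0, ncol = 3,
                                         dimnames = list(NULL, c("wt", "missense", "deletion")))) {
  new("SimConfig",
      seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
      chromLengthBp = as.integer(chromLengthBp),
      nRepeatElements = as.integer(nRepeatElements),
      repnameCatalog = as.data.frame(repnameCatalog),
      nGenes = as.integer(nGenes),
      nSamplesPerGroup = as.integer(nSamplesPerGroup),
      meanDepthFragments = as.integer(meanDepthFragments),
      nbDispersion = as.numeric(nbDispersion),
      effectLog2FC = effectLog2FC,
      dnaContaminationFraction = as.numeric(dnaContaminationFraction),
      batchStrength = as.numeric(batchStrength),
      alleleMix = alleleMix)
}

#' Default repeat catalog
#'
#' A small three-level RepeatMasker-style catalog covering the element
#' classes the analysis distinguishes: LTR retrotransposons (IAP, MERVL),
#' a LINE and a SINE, two DNA transposons (the contamination readout), and
#' one Simple_repeat and one Low_complexity entry (to exercise their
#' exclusion on loading).
#'
#' @return data.frame with repName, repFamily, repClass.
#' @export
defaultRepeatCatalog <- function() {
  data.frame(
    repName = c("IAPEz-int", "IAPLTR1_Mm", "MERVL-int", "MT2_Mm",
                 "L1MdTf_I", "B1_Mm", "Tigger1", "Charlie1a",
                 "(CA)n", "A-rich"),
    repFamily = c("ERVK", "ERVK", "ERVL", "ERVL",
                   "L1", "Alu", "TcMar-Tigger", "hAT-Charlie",
                   "Simple_repeat", "Low_complexity"),
    repClass = c("LTR", "LTR", "LTR", "LTR",
                  "LINE", "SINE", "DNA", "DNA",
                  "Simple_repeat", "Low_complexity"),
    stringsAsFactors = FALSE)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "|",
      object@nChromosomes, "autosome(s) x", object@chromLengthBp, "bp |",
      object@nRepeatElements, "repeat elements /",
      nrow(object@repnameCatalog), "repNames |",
      object@nGenes, "genes |",
      object@nSamplesPerGroup, "samples/group\n")
})

#' Paired-end fragments as two parallel mate ranges
#'
#' A light container for aligned paired-end fragments: two parallel
#' \link[GenomicRanges]{GRanges} of mate intervals plus fragment names.
#' Mates of a counted fragment must lie on the same chromosome.
#'
#' @slot first,second GRanges of mate intervals (parallel).
#' @export
setClass("PairedFragments", representation(
  first = "GRanges", second = "GRanges"))

setValidity("PairedFragments", function(object) {
  if (length(object@first) != length(object@second))
    return("mate vectors differ in length")
  TRUE
})

#' Construct PairedFragments
#' @param first,second parallel GRanges of mate intervals.
#' @param names optional fragment (read pair) names.
#' @return A \linkS4class{PairedFragments}.
#' @export
PairedFragments <- function(first, second, names = NULL) {
  if (!is.null(names)) {
    names(first) <- names
    names(second) <- names
  }
  new("PairedFragments", first = first, second = second)
}

#' @describeIn PairedFragments-class first mates
#' @param x a PairedFragments
#' @export
firstMate <- function(x) x@first

#' @describeIn PairedFragments-class second mates
#' @export
secondMate <- function(x) x@second

setMethod("length", "PairedFragments", function(x) length(x@first))

setMethod("show", "PairedFragments", function(object) {
  cat("PairedFragments with", length(object), "fragments on",
      length(unique(as.character(GenomicRanges::seqnames(object@first)))),
      "sequence(s)\n")
})

#' Per-repName fragment counts with summarized lengths
#'
#' Fragment counts per repName and sample, the summarized length of each
#' repName (sum of its element lengths, in kb) and the per-sample aligner
#' input read count, i.e. everything the FPKM formulas consume.
#'
#' @slot counts integer matrix, repNames x samples.
#' @slot lengthKb named numeric, summarized length per repName (kb).
#' @slot inputReads named numeric, aligner input reads per sample.
#' @slot nameToFamily,nameToClass named character maps.
#' @slot ambiguousFragments named numeric, per-sample count of discarded
#'   fragments whose mates fell in elements of different repNames.
#' @export
setClass("RepeatCountTable", representation(
  counts = "matrix",
  lengthKb = "numeric",
  inputReads = "numeric",
  nameToFamily = "character",
  nameToClass = "character",
  ambiguousFragments = "numeric"))

setValidity("RepeatCountTable", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (!identical(rownames(object@counts), names(object@lengthKb)))
    msg <- c(msg, "rownames(counts) must match names(lengthKb)")
  counted <- rownames(object@counts)[rowSums(object@counts) > 0]
  if (any(object@lengthKb[counted] <= 0))
    msg <- c(msg, "summarized length must be > 0 for counted repNames")
  if (!identical(colnames(object@counts), names(object@inputReads)))
    msg <- c(msg, "colnames(counts) must match names(inputReads)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RepeatCountTable", function(object) {
  cat("RepeatCountTable:", nrow(object@counts), "repNames x",
      ncol(object@counts), "sample(s);",
      sum(object@counts), "fragments counted,",
      sum(object@ambiguousFragments), "ambiguous discarded\n")
})

#' @describeIn RepeatCountTable-class count matrix
#' @param object a RepeatCountTable
#' @export
repeatCounts <- function(object) object@counts

#' @describeIn RepeatCountTable-class summarized lengths (kb)
#' @export
summarizedLengthKb <- function(object) object@lengthKb

#' @describeIn RepeatCountTable-class aligner input reads per sample
#' @export
inputReadCount <- function(object) object@inputReads

#' FPKM values at repName or repFamily level
#'
#' @slot level "repName" or "repFamily".
#' @slot fpkm numeric matrix, features x samples.
#' @slot dnaFpkm named numeric, per-sample sum of FPKM over DNA-class
#'   features (the contamination covariate); filled by
#'   \code{\link{dnaContamination}}.
#' @slot featureClass named character, repClass per feature.
#' @export
setClass("FpkmTable", representation(
  level = "character",
  fpkm = "matrix",
  dnaFpkm = "numeric",
  featureClass = "character"))

setValidity("FpkmTable", function(object) {
  msg <- character()
  if (!object@level %in% c("repName", "repFamily"))
    msg <- c(msg, "level must be repName or repFamily")
  if (any(object@fpkm < 0)) msg <- c(msg, "FPKM must be non-negative")
  if (length(object@dnaFpkm) && any(object@dnaFpkm < 0))
    msg <- c(msg, "dnaFpkm must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FpkmTable", function(object) {
  cat("FpkmTable (", object@level, "): ", nrow(object@fpkm), " features x ",
      ncol(object@fpkm), " sample(s)\n", sep = "")
})

#' @describeIn FpkmTable-class FPKM matrix
#' @param object an FpkmTable
#' @export
fpkmValues <- function(object) object@fpkm

#' @describeIn FpkmTable-class per-sample DNA-class FPKM sum
#' @export
dnaFpkm <- function(object) object@dnaFpkm

#' Differential-expression result table
#'
#' One row per feature: mean normalized count, unshrunken log2 fold change
#' (MLE), its standard error, the Wald statistic, raw and BH-adjusted
#' p-values and the independent-filtering flag.
#'
#' @slot results DataFrame with columns baseMean, log2FoldChange, lfcSE,
#'   stat, pvalue, padj, filtered.
#' @slot coefName tested coefficient.
#' @slot dispersions named numeric, final (moderated) per-feature dispersion.
#' @export
setClass("DEResult", representation(
  results = "DFrame", coefName = "character", dispersions = "numeric"))

setValidity("DEResult", function(object) {
  r <- object@results
  need <- c("baseMean", "log2FoldChange", "lfcSE", "stat", "pvalue", "padj",
            "filtered")
  if (!all(need %in% colnames(r)))
    return(paste("missing columns:", paste(setdiff(need, colnames(r)), collapse = ", ")))
  ok <- !is.na(r$padj) & !is.na(r$pvalue)
  if (any(r$padj[ok] < r$pvalue[ok] - 1e-12))
    return("padj must be >= pvalue")
  TRUE
})

setMethod("show", "DEResult", function(object) {
  r <- object@results
  cat("DEResult on coefficient '", object@coefName, "': ", nrow(r),
      " features; ", sum(!is.na(r$padj) & r$padj < 0.05),
      " at padj < 0.05 (", sum(r$filtered), " filtered)\n", sep = "")
})

#' @describeIn DEResult-class result table as a DataFrame
#' @param object a DEResult
#' @export
deTable <- function(object) object@results

#' Factors of unwanted variation
#'
#' @slot W samples x k matrix of unwanted-variation factors (orthogonal
#'   columns), suitable as design covariates.
#' @slot controlGenes control gene ids used.
#' @export
setClass("RuvFactors", representation(W = "matrix", controlGenes = "character"))

setValidity("RuvFactors", function(object) {
  W <- object@W
  if (ncol(W) > 1) {
    cp <- crossprod(W)
    off <- cp - diag(diag(cp), ncol(cp))
    if (max(abs(off)) > 1e-6 * max(1, max(abs(diag(cp)))))
      return("columns of W must be orthogonal")
  }
  TRUE
})

setMethod("show", "RuvFactors", function(object) {
  cat("RuvFactors: k =", ncol(object@W), "factors over", nrow(object@W),
      "samples, from", length(object@controlGenes), "control genes\n")
})

#' @describeIn RuvFactors-class the W matrix
#' @param object a RuvFactors
#' @export
ruvW <- function(object) object@W
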