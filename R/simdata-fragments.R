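#' Simulate aligned paired-end fragments with known provenance
#'
#' Draws sequenced fragments feature-by-feature (repeat elements and gene
#' bodies) proportionally to rate x length, adds genomic-DNA contaminant
#' fragments drawn uniformly over DNA-class elements, optionally places a
#' fraction of repeat-derived fragments straddling the element boundary (to
#' exercise the containment filter), and optionally emits single-end reads
#' over the mutated codon with the configured allele mixture; deletion-allele
#' reads carry a 3-bp-shorter matching segment represented as a soft-clipped
#' tail, never as an in-read deletion operation. Every fragment carries
#' exactly one provenance label.
#'
#' @param config a \linkS4class{SimConfig}; \code{meanDepthFragments} sets
#'   the expected fragment count and \code{dnaContaminationFraction[1]} the
#'   contaminant fraction.
#' @param annotation output of \code{\link{makeToyAnnotation}}.
#' @param rates named non-negative per-feature expression rates over
#'   \code{c(elementId, gene_id)}; default all 1.
#' @param straddleFraction fraction of repeat fragments placed straddling
#'   their element's 3' boundary; default 0.05.
#' @param alleleFractions length-3 numeric (wt, missense, deletion) or NULL.
#' @param nLocusReads single-end reads to emit over the mutated codon.
#' @param samPath optional path; when given, a coordinate-sorted headered
#'   SAM file is written there.
#' @param readLen,insertSize read and fragment geometry (bp).
#' @param sampleName read-name prefix.
#' @param rateDispersion biological variability of feature rates between
#'   samples: each feature's rate is multiplied by a Gamma(1/d, d)
#'   variate, making fragment counts marginally negative-binomial with
#'   dispersion about d across samples. Defaults to the config's
#'   \code{nbDispersion}; set 0 for deterministic rates.
#' @return list: \code{fragments} (\linkS4class{PairedFragments}),
#'   \code{truth} (data.frame qname/provenance), \code{locusReads}
#'   (data.frame qname/allele/seq/cigar/pos or NULL), \code{samPath}.
#' @export
simulateFragments <- function(config, annotation, rates = NULL,
                              straddleFraction = 0.05,
                              alleleFractions = NULL, nLocusReads = 0L,
                              samPath = NULL, readLen = 50L,
                              insertSize = 250L, sampleName = "s1",
                              rateDispersion = NULL) {
  stopifnot(is(config, "SimConfig"))
  repeats <- annotation$repeats
  genes <- annotation$genes
  featIds <- c(repeats$elementId, genes$gene_id)
  featChrom <- c(as.character(GenomicRanges::seqnames(repeats)),
                 as.character(GenomicRanges::seqnames(genes)))
  featStart <- c(BiocGenerics::start(repeats), BiocGenerics::start(genes))
  featEnd <- c(BiocGenerics::end(repeats), BiocGenerics::end(genes))
  isRep <- c(rep(TRUE, length(repeats)), rep(FALSE, length(genes)))

  if (is.null(rates)) rates <- setNames(rep(1, length(featIds)), featIds)
  if (any(rates < 0)) stop("rates must be non-negative")
  r <- setNames(numeric(length(featIds)), featIds)
  r[names(rates)] <- rates
  w <- r * (featEnd - featStart + 1L)

  dnaIdx <- which(isRep & repeats$repClass[match(featIds, repeats$elementId)] == "DNA")
  dnaFrac <- config@dnaContaminationFraction[1]

  if (is.null(rateDispersion)) rateDispersion <- config@nbDispersion

  withStream(config@seed, paste0("fragments:", sampleName), {
    if (rateDispersion > 0) {
      noise <- stats::rgamma(length(w), shape = 1 / rateDispersion,
                             scale = rateDispersion)
      w <- w * noise
    }
    N <- config@meanDepthFragments
    nContam <- if (length(dnaIdx) && dnaFrac > 0) rbinom(1L, N, dnaFrac) else 0L
    nExpr <- N - nContam
    if (sum(w) <= 0 && nExpr > 0) stop("all feature rates are zero")
    nPer <- as.vector(rmultinom(1, nExpr, w / sum(w)))
    contamFeat <- if (nContam > 0) sample(dnaIdx, nContam, replace = TRUE) else integer(0)

    featOf <- c(rep(seq_along(featIds), nPer), contamFeat)
    prov <- c(rep(ifelse(isRep, paste0("repeat:", featIds),
                         paste0("gene:", featIds)), nPer),
              rep("dna_contaminant", nContam))
    n <- length(featOf)
    if (n == 0L) {
      frags <- PairedFragments(GenomicRanges::GRanges(), GenomicRanges::GRanges())
      truth <- data.frame(qname = character(0), provenance = character(0))
    } else {
      fs <- featStart[featOf]; fe <- featEnd[featOf]
      fw <- fe - fs + 1L
      span <- pmin(insertSize, fw)
      span <- pmax(span, readLen)
      ## fragment start inside the feature
      s <- fs + floor(runif(n) * pmax(fw - span + 1L, 1L))
      ## straddling: repeat-derived, non-contaminant fragments only
      canStraddle <- isRep[featOf] & prov != "dna_contaminant"
      doStraddle <- canStraddle & runif(n) < straddleFraction
      s[doStraddle] <- fe[doStraddle] - span[doStraddle] + readLen %/% 2L
      e <- s + span - 1L
      qname <- paste0(sampleName, "_f", seq_len(n))
      chr <- featChrom[featOf]
      m1 <- GenomicRanges::GRanges(chr, IRanges::IRanges(start = s, width = readLen))
      m2 <- GenomicRanges::GRanges(chr, IRanges::IRanges(end = e, width = readLen))
      frags <- PairedFragments(m1, m2, names = qname)
      truth <- data.frame(qname = qname, provenance = prov,
                          stringsAsFactors = FALSE)
    }

    locus <- NULL
    if (nLocusReads > 0L) {
      if (is.null(alleleFractions)) stop("alleleFractions required for locus reads")
      locus <- simulateLocusReads(annotation, alleleFractions, nLocusReads,
                                  readLen = readLen, prefix = sampleName)
    }

    if (!is.null(samPath))
      writeSimSam(samPath, annotation$chromLengths, frags, locus,
                  readLen = readLen)

    list(fragments = frags, truth = truth, locusReads = locus,
         samPath = samPath)
  })
}

## Single-end reads over the mutated codon. Deletion reads are substrings of
## the deletion template; their CIGAR matches up to the codon and soft-clips
## the remainder (mirroring how an end-to-end aligner without indel search
## represents the 3-bp deletion).
simulateLocusReads <- function(annotation, alleleFractions, nReads,
                               readLen = 50L, prefix = "s1") {
  stopifnot(length(alleleFractions) == 3L,
            abs(sum(alleleFractions) - 1) < 1e-8)
  tpl <- alleleTemplates(annotation, flank = max(60L, readLen + 10L))
  ml <- annotation$mutLocus
  flank <- max(60L, readLen + 10L)
  codonPos <- flank + 1L  # codon offset within templates (1-based)
  alleles <- sample(c("WT", "missense", "deletion"), nReads, replace = TRUE,
                    prob = alleleFractions)
  ## read start offset within template: codon covered with >= 10 bp margin
  lo <- codonPos - (readLen - 13L)
  hi <- codonPos - 10L
  off <- floor(runif(nReads, lo, hi + 1L))
  seqs <- character(nReads); cig <- character(nReads); pos <- integer(nReads)
  for (i in seq_len(nReads)) {
    t <- tpl[[alleles[i]]]
    seqs[i] <- substr(t, off[i], off[i] + readLen - 1L)
    genomeStart <- ml$codonStart - flank  # template origin on the chromosome
    pos[i] <- genomeStart + off[i] - 1L
    if (alleles[i] == "deletion") {
      m <- codonPos - off[i]  # bases matching before the deleted codon
      cig[i] <- paste0(m, "M", readLen - m, "S")
    } else {
      cig[i] <- paste0(readLen, "M")
    }
  }
  data.frame(qname = paste0(prefix, "_locus", seq_len(nReads)),
             allele = alleles, seq = seqs, cigar = cig, pos = pos,
             chrom = ml$chrom, stringsAsFactors = FALSE)
}

## Emit a coordinate-sorted, headered SAM file: paired fragment records
## (flags 99/147, CIGAR all-match, SEQ omitted) plus optional single-end
## locus reads carrying sequence and soft-clip CIGARs. SAM is 1-based.
writeSimSam <- function(path, chromLengths, fragments, locusReads = NULL,
                        readLen = 50L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(chromLengths), "\tLN:",
                  as.integer(chromLengths)))
  recs <- data.frame(rname = character(0), pos = integer(0),
                     line = character(0), stringsAsFactors = FALSE)
  if (length(fragments) > 0) {
    m1 <- firstMate(fragments); m2 <- secondMate(fragments)
    qn <- names(m1)
    chr <- as.character(GenomicRanges::seqnames(m1))
    p1 <- BiocGenerics::start(m1); p2 <- BiocGenerics::start(m2)
    w1 <- GenomicRanges::width(m1); w2 <- GenomicRanges::width(m2)
    tlen <- BiocGenerics::end(m2) - p1 + 1L
    l1 <- paste(qn, 99L, chr, p1, 255L, paste0(w1, "M"), "=", p2, tlen,
                "*", "*", sep = "\t")
    l2 <- paste(qn, 147L, chr, p2, 255L, paste0(w2, "M"), "=", p1, -tlen,
                "*", "*", sep = "\t")
    recs <- rbind(recs,
                  data.frame(rname = chr, pos = p1, line = l1),
                  data.frame(rname = chr, pos = p2, line = l2))
  }
  if (!is.null(locusReads) && nrow(locusReads) > 0) {
    ll <- paste(locusReads$qname, 0L, locusReads$chrom, locusReads$pos, 255L,
                locusReads$cigar, "*", 0L, 0L, locusReads$seq,
                "*", sep = "\t")
    recs <- rbind(recs, data.frame(rname = locusReads$chrom,
                                   pos = locusReads$pos, line = ll))
  }
  ord <- order(match(recs$rname, names(chromLengths)), recs$pos)
  writeLines(c(hdr, recs$line[ord]), path)
  invisible(path)
}
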