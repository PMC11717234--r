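#' Generate a toy genome with repeat and gene annotations
#'
#' Builds a small random genome (autosome-like chromosomes plus chrY and
#' chrM), places non-overlapping repeat elements drawn from the repName
#' catalog and non-overlapping gene bodies, and designates Y-linked,
#' mitochondrial and rDNA-proxy genes as well as one autosomal gene
#' carrying the mutated codon used for allele calling. The genome is random
#' sequence: only interval and sequence mechanics matter downstream, no
#' biological realism is claimed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param overlapFraction fraction of repeat elements deliberately relocated
#'   inside gene bodies (to exercise the gene-overlap exclusion); default 0.
#' @return list with elements \code{repeats} (GRanges with
#'   repName/repFamily/repClass and element ids), \code{genes} (GRanges with
#'   gene_id, geneType in standard/y_linked/mito/rdna, lengthKb),
#'   \code{genome} (DNAStringSet), \code{chromLengths} (named integer) and
#'   \code{mutLocus} (list: gene, chrom, codonStart, codonEnd, 1-based
#'   closed coordinates of the mutated codon).
#' @examples
#' ann <- makeToyAnnotation(SimConfig(seed = 1))
#' length(ann$repeats)
#' @export
makeToyAnnotation <- function(config, overlapFraction = 0) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  cat. <- config@repnameCatalog
  if (config@nRepeatElements < nrow(cat.))
    stop("nRepeatElements must be >= number of catalog repNames")

  nChr <- config@nChromosomes
  chromLengths <- setNames(rep(config@chromLengthBp, nChr),
                           paste0("chr", seq_len(nChr)))
  chromLengths["chrY"] <- max(config@chromLengthBp %/% 2L, 50000L)
  chromLengths["chrM"] <- 16299L

  withStream(config@seed, "annotation", {
    ## element widths and labels: every repName appears at least once
    idx <- c(seq_len(nrow(cat.)),
             sample.int(nrow(cat.), config@nRepeatElements - nrow(cat.),
                        replace = TRUE))
    repWidths <- as.integer(round(runif(config@nRepeatElements, 500, 3000)))
    geneWidths <- as.integer(round(runif(config@nGenes, 1000, 4000)))

    autosomes <- names(chromLengths)[seq_len(nChr)]
    repChrom <- autosomes[(seq_len(config@nRepeatElements) - 1L) %% nChr + 1L]
    geneChrom <- autosomes[(seq_len(config@nGenes) - 1L) %% nChr + 1L]

    placeOn <- function(chrom, widths) {
      L <- chromLengths[[chrom]]
      n <- length(widths)
      if (n == 0L) return(integer(0))
      free <- L - sum(widths) - n  # keep >= ~1 bp spare per element
      if (free < n)
        stop("chromosome ", chrom, " too short (", L, " bp) to place ", n,
             " elements totalling ", sum(widths), " bp")
      gaps <- as.vector(rmultinom(1, free, rep(1, n + 1L)))
      starts <- integer(n)
      pos <- 1L
      for (i in seq_len(n)) {
        pos <- pos + gaps[i]
        starts[i] <- pos
        pos <- pos + widths[i] + 1L
      }
      starts
    }

    ## interleave repeats and genes per autosome so neither overlaps
    repStart <- integer(config@nRepeatElements)
    geneStart <- integer(config@nGenes)
    for (chrom in autosomes) {
      ri <- which(repChrom == chrom)
      gi <- which(geneChrom == chrom)
      widths <- c(repWidths[ri], geneWidths[gi])
      ord <- sample.int(length(widths))
      starts <- placeOn(chrom, widths[ord])
      starts[ord] <- starts
      repStart[ri] <- starts[seq_along(ri)]
      geneStart[gi] <- starts[length(ri) + seq_along(gi)]
    }

    repeats <- GenomicRanges::GRanges(
      seqnames = repChrom,
      ranges = IRanges::IRanges(start = repStart, width = repWidths),
      strand = sample(c("+", "-"), config@nRepeatElements, replace = TRUE),
      repName = cat.$repName[idx],
      repFamily = cat.$repFamily[idx],
      repClass = cat.$repClass[idx],
      elementId = paste0("rep_e", seq_len(config@nRepeatElements)))

    ## optional: relocate a fraction of repeats inside gene bodies
    nOv <- round(overlapFraction * length(repeats))
    if (nOv > 0) {
      pick <- sample.int(length(repeats), nOv)
      for (i in pick) {
        g <- sample.int(config@nGenes, 1L)
        w <- min(GenomicRanges::width(repeats)[i], geneWidths[g] - 2L)
        s <- geneStart[g] + sample.int(max(geneWidths[g] - w, 1L), 1L) - 1L
        repeats[i] <- GenomicRanges::GRanges(
          geneChrom[g], IRanges::IRanges(start = s, width = w),
          strand = BiocGenerics::strand(repeats)[i],
          repName = repeats$repName[i], repFamily = repeats$repFamily[i],
          repClass = repeats$repClass[i], elementId = repeats$elementId[i])
      }
    }

    ## special genes: Y-linked pair, mitochondrial trio, rDNA proxy
    yWidths <- c(2000L, 2200L)
    yStarts <- placeOn("chrY", yWidths)
    mtWidths <- c(950L, 1500L, 1140L)
    mtStarts <- placeOn("chrM", mtWidths)

    geneIds <- paste0("gene", seq_len(config@nGenes))
    geneType <- rep("standard", config@nGenes)
    ## the rDNA proxy is one designated autosomal gene
    geneType[1L] <- "rdna"
    geneIds[1L] <- "Rn45s"
    ## the mutation-target gene (allele calling locus)
    mutIdx <- 2L
    geneIds[mutIdx] <- "Ogt"

    genes <- GenomicRanges::GRanges(
      seqnames = c(geneChrom, "chrY", "chrY", rep("chrM", 3L)),
      ranges = IRanges::IRanges(
        start = c(geneStart, yStarts, mtStarts),
        width = c(geneWidths, yWidths, mtWidths)),
      strand = "+",
      gene_id = c(geneIds, "Ddx3y", "Eif2s3y", "mt-Nd1", "mt-Co1", "mt-Cytb"),
      geneType = c(geneType, "y_linked", "y_linked", rep("mito", 3L)))
    genes$lengthKb <- GenomicRanges::width(genes) / 1000

    genome <- Biostrings::DNAStringSet(vapply(chromLengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)))
    names(genome) <- names(chromLengths)

    ## mutated codon at the center of the target gene
    tgt <- genes[genes$gene_id == "Ogt"]
    codonStart <- BiocGenerics::start(tgt) +
      (GenomicRanges::width(tgt) %/% 2L)
    mutLocus <- list(gene = "Ogt",
                     chrom = as.character(GenomicRanges::seqnames(tgt)),
                     codonStart = codonStart,
                     codonEnd = codonStart + 2L)

    list(repeats = repeats, genes = genes, genome = genome,
         chromLengths = chromLengths, mutLocus = mutLocus)
  })
}

#' Allele templates over the mutated codon
#'
#' Builds the WT, missense and deletion template sequences over a window
#' centred on the mutated codon. The missense template substitutes the first
#' codon base; the deletion template is the WT window with the 3-bp codon
#' removed, so that a read carrying the deletion matches the WT sequence up
#' to the codon and then the post-deletion junction.
#'
#' @param annotation output of \code{\link{makeToyAnnotation}}.
#' @param flank bases on each side of the codon; default 50.
#' @return named character vector (WT, missense, deletion).
#' @export
alleleTemplates <- function(annotation, flank = 50L) {
  ml <- annotation$mutLocus
  chromSeq <- as.character(annotation$genome[[ml$chrom]])
  a <- ml$codonStart - flank
  b <- ml$codonEnd + flank
  wt <- substr(chromSeq, a, b)
  codonPos <- flank + 1L
  sub <- chartr("ACGT", "GTAC", substr(wt, codonPos, codonPos))
  missense <- paste0(substr(wt, 1, codonPos - 1L), sub,
                     substr(wt, codonPos + 1L, nchar(wt)))
  deletion <- paste0(substr(wt, 1, codonPos - 1L),
                     substr(wt, codonPos + 3L, nchar(wt)))
  c(WT = wt, missense = missense, deletion = deletion)
}
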