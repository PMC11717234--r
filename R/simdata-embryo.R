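#' Simulate a single-embryo RNA-seq cohort with genotyping inputs
#'
#' Generates everything the embryo QC/genotyping stage consumes: a gene
#' count matrix per embryo (negative-binomial, genotype effect per
#' \code{effectLog2FC}), Y-linked gene counts for designated males (zero
#' plus optional noise for females), mitochondrial and rDNA-proxy counts set
#' to configured fractions (including deliberate outliers), total library
#' depths, degron-tag-mapping read counts, and single-end reads over the
#' mutated codon following each embryo's allele mixture (deletion reads as
#' soft-clipped records).
#'
#' @param config a \linkS4class{SimConfig}. When \code{alleleMix} has rows
#'   they define the per-embryo allele fractions (and the cohort size);
#'   otherwise the first half of embryos is WT (1,0,0) and the second half
#'   carries the deletion (0,0,1).
#' @param sexes character vector ("male"/"female") per embryo; default
#'   alternating.
#' @param yGeneRate Poisson mean per Y-linked gene in males; default 30.
#' @param yNoiseRate Poisson mean per Y-linked gene in females; default 0.
#' @param totalReads per-embryo library depth (aligner input reads),
#'   recycled; default 2e6.
#' @param mtFraction,rdnaFraction per-embryo fractions, recycled; set single
#'   entries high to construct outliers.
#' @param tagged logical per embryo: carries the degron tag; default
#'   \code{genotype != "WT"}.
#' @param tagReadsTagged,tagReadsWT Poisson means of tag-mapping reads.
#' @param nLocusReads reads over the mutated codon per embryo.
#' @param annotation optional \code{\link{makeToyAnnotation}} output
#'   (generated from \code{config} if NULL).
#' @return list: \code{se} (SummarizedExperiment, genes x embryos, colData
#'   holding all truth fields), \code{locusReads} (named list of per-embryo
#'   read data.frames), \code{truth} (data.frame: sample, sex, genotype,
#'   alleleMix columns, totalReads, mtFraction, rdnaFraction, tagReads,
#'   tagged, belowDepth), \code{annotation}.
#' @export
simulateEmbryoCohort <- function(config, sexes = NULL, yGeneRate = 30,
                                 yNoiseRate = 0, totalReads = 2e6,
                                 mtFraction = 0.05, rdnaFraction = 0.03,
                                 tagged = NULL, tagReadsTagged = 500,
                                 tagReadsWT = 2, nLocusReads = 30L,
                                 annotation = NULL) {
  stopifnot(is(config, "SimConfig"))
  if (is.null(annotation)) annotation <- makeToyAnnotation(config)

  am <- config@alleleMix
  if (nrow(am) == 0L) {
    n <- 2L * config@nSamplesPerGroup
    am <- rbind(matrix(rep(c(1, 0, 0), each = n %/% 2L), ncol = 3),
                matrix(rep(c(0, 0, 1), each = n - n %/% 2L), ncol = 3))
    colnames(am) <- c("wt", "missense", "deletion")
  }
  n <- nrow(am)
  genotype <- apply(am, 1, function(p) {
    if (p[1] >= 1 - 1e-8) "WT"
    else if (sum(p > 1e-8) >= 2L) "heterozygous"
    else if (p[2] >= 1 - 1e-8) "missense" else "deletion"
  })
  if (is.null(sexes)) sexes <- rep(c("male", "female"), length.out = n)
  stopifnot(length(sexes) == n, all(sexes %in% c("male", "female")))
  totalReads <- rep(totalReads, length.out = n)
  mtFraction <- rep(mtFraction, length.out = n)
  rdnaFraction <- rep(rdnaFraction, length.out = n)
  if (is.null(tagged)) tagged <- genotype != "WT"
  tagged <- rep(tagged, length.out = n)

  ## genotype drives the group label of the count model
  design <- data.frame(group = factor(ifelse(genotype == "WT", "ctrl", "mut"),
                                      levels = c("ctrl", "mut")))
  geneIds <- annotation$genes$gene_id
  se <- simulateCounts(config, design = design, featureIds = geneIds,
                       streamLabel = "embryo-counts")
  counts <- SummarizedExperiment::assay(se, "counts")
  sampleIds <- paste0("embryo", seq_len(n))
  colnames(counts) <- sampleIds

  withStream(config@seed, "embryo-special", {
    gt <- annotation$genes$geneType
    yIdx <- which(gt == "y_linked")
    mtIdx <- which(gt == "mito")
    rdIdx <- which(gt == "rdna")
    depthScale <- totalReads / mean(totalReads)
    for (j in seq_len(n)) {
      yMean <- if (sexes[j] == "male") yGeneRate else yNoiseRate
      counts[yIdx, j] <- rpois(length(yIdx), yMean * depthScale[j])
      lib <- sum(counts[-c(mtIdx, rdIdx), j])
      counts[mtIdx, j] <- round(mtFraction[j] * lib / length(mtIdx))
      counts[rdIdx, j] <- round(rdnaFraction[j] * lib / length(rdIdx))
    }
    tagReads <- ifelse(tagged, rpois(n, tagReadsTagged), rpois(n, tagReadsWT))

    locusReads <- lapply(seq_len(n), function(j) {
      withStream(config@seed, paste0("locus:", sampleIds[j]),
                 simulateLocusReads(annotation, am[j, ], nLocusReads,
                                    prefix = sampleIds[j]))
    })
    names(locusReads) <- sampleIds

    truth <- data.frame(sample = sampleIds, sex = sexes, genotype = genotype,
                        wtFrac = am[, 1], missenseFrac = am[, 2],
                        deletionFrac = am[, 3], totalReads = totalReads,
                        mtFraction = mtFraction, rdnaFraction = rdnaFraction,
                        tagReads = tagReads, tagged = tagged,
                        belowDepth = totalReads < 1e6,
                        stringsAsFactors = FALSE)

    cd <- S4Vectors::DataFrame(truth[, -1], row.names = sampleIds)
    out <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts), colData = cd,
      rowData = SummarizedExperiment::rowData(se),
      metadata = S4Vectors::metadata(se))
    list(se = out, locusReads = locusReads, truth = truth,
         annotation = annotation)
  })
}
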