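## Orchestration of the two study-shaped workflows over synthetic data.
## Each stage is wrapped so that a failure aborts with the stage name while
## keeping whatever outputs were already written.

defaultThresholds <- function() {
  list(degAlpha = 0.05,   # single-copy genes called at padj < 0.05
       teAlpha = 0.1,     # repeats called at padj < 0.1
       filterAlpha = 0.05,  # independent-filtering optimization cutoff
       depthMin = 1e6, ruvK = 6L, tagCutoff = 72L,
       sexThreshold = 10, madK = 3)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

## Shared TE-quantification stage: per sample, simulate fragments (planted
## family effect in mutants), write SAM, read it back, filter, count.
.teQuantStage <- function(config, ann, sampleIds, isMutant, teEffectLog2FC,
                          outDir, straddleFraction = 0.05) {
  samDir <- file.path(outDir, "sam")
  dir.create(samDir, showWarnings = FALSE, recursive = TRUE)
  baseRates <- setNames(rep(1, length(ann$repeats) + length(ann$genes)),
                        c(ann$repeats$elementId, ann$genes$gene_id))
  mutRates <- baseRates
  if (length(teEffectLog2FC)) {
    for (fam in names(teEffectLog2FC)) {
      el <- ann$repeats$elementId[ann$repeats$repFamily == fam]
      mutRates[el] <- mutRates[el] * 2^teEffectLog2FC[[fam]]
    }
  }
  ## quantify against the loading convention: simple/low-complexity repeats
  ## exist in the simulation but are excluded from counting
  quantRepeats <- ann$repeats[!ann$repeats$repClass %in%
                                c("Simple_repeat", "Low_complexity")]
  tabs <- lapply(seq_along(sampleIds), function(j) {
    sm <- sampleIds[j]
    samPath <- file.path(samDir, paste0(sm, ".sam"))
    sim <- simulateFragments(config, ann,
                             rates = if (isMutant[j]) mutRates else baseRates,
                             straddleFraction = straddleFraction,
                             samPath = samPath, sampleName = sm)
    frags <- readFragmentsSam(samPath)
    kept <- filterRepeatFragments(frags, quantRepeats, ann$genes)
    countByRepName(kept, quantRepeats,
                   inputReads = 2 * length(frags), sampleName = sm)
  })
  bindRepeatCounts(tabs)
}

#' Run the single-embryo blastocyst workflow on synthetic data
#'
#' Executes the full study-shaped chain: cohort simulation, embryo QC
#' (depth and mt/rDNA outlier filters), in-silico sexing and genotyping
#' (tag counts and allele calling at the mutated codon), size factors, gene
#' differential expression (with unwanted-variation factors when batch
#' structure is present), repeat quantification from per-embryo SAM files
#' with the DNA-contamination covariate, repeat differential expression at
#' the repeat significance threshold, signed ranking, GSEA and
#' developmental-delay statistics. Writes flat TSV outputs plus a
#' machine-readable JSON report (counts of embryos kept/discarded by
#' reason, DEG counts, a determinism hash) and returns the report.
#'
#' @param config a \linkS4class{SimConfig}; its seed drives every stage.
#' @param outDir output directory.
#' @param teEffectLog2FC named numeric of planted repFamily effects in
#'   mutants, e.g. \code{c(ERVK = log2(1.5))}; default none.
#' @param thresholds list as \code{defaultThresholds()}.
#' @param geneSets named list of gene sets; default toy sets including one
#'   planted from the true effects.
#' @param nPerm GSEA permutations; default 1000.
#' @param cohortArgs extra arguments forwarded to
#'   \code{\link{simulateEmbryoCohort}} (e.g. deliberate depth or
#'   mt-fraction outliers).
#' @return (invisibly) the report list.
#' @export
runEmbryoWorkflow <- function(config, outDir,
                              teEffectLog2FC = numeric(0),
                              thresholds = defaultThresholds(),
                              geneSets = NULL, nPerm = 1000L,
                              cohortArgs = list()) {
  th <- utils::modifyList(defaultThresholds(), thresholds)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(workflow = "embryo", seed = config@seed)

  ann <- .stage("annotation", makeToyAnnotation(config))
  cohort <- .stage("cohort-simulation",
                   do.call(simulateEmbryoCohort,
                           c(list(config = config, annotation = ann),
                             cohortArgs)))
  counts <- SummarizedExperiment::assay(cohort$se, "counts")
  truth <- cohort$truth

  ## embryo QC: depth from the configured library size, mt/rDNA fractions
  ## recomputed from the observed counts
  qc <- .stage("embryo-qc", {
    gt <- ann$genes$geneType
    tot <- colSums(counts)
    rec <- data.frame(
      sample = truth$sample, totalReads = truth$totalReads,
      mtFraction = colSums(counts[gt == "mito", , drop = FALSE]) / tot,
      rdnaFraction = colSums(counts[gt == "rdna", , drop = FALSE]) / tot)
    qcFilterEmbryos(rec, depthMin = th$depthMin, madK = th$madK)
  })
  writeTsv(qc$kept, file.path(outDir, "embryo_qc_kept.tsv"))
  if (nrow(qc$discarded))
    writeTsv(qc$discarded, file.path(outDir, "embryo_qc_discarded.tsv"))
  kept <- qc$kept$sample
  report$embryos <- list(total = nrow(truth), kept = length(kept),
                         discardedByReason = as.list(table(unlist(
                           strsplit(qc$discarded$reasons, ";")))))

  geno <- .stage("sexing-genotyping", {
    cm <- counts[, kept, drop = FALSE]
    sf <- sizeFactorsMedianRatios(cm)
    nc <- normalizedCounts(cm, sf)
    sex <- assignSex(nc, c("Ddx3y", "Eif2s3y"), threshold = th$sexThreshold)
    tagCall <- genotypeFromTagCounts(truth$tagReads[match(kept, truth$sample)],
                                     cutoff = th$tagCutoff)
    tpl <- alleleTemplates(ann)
    allele <- lapply(kept, function(sm)
      callAlleleAtLocus(cohort$locusReads[[sm]], tpl))
    data.frame(sample = kept, score = sex$score, sexCall = sex$sexCall,
               tagCall = tagCall,
               alleleCall = vapply(allele, `[[`, character(1), "call"),
               nInformative = vapply(allele, `[[`, numeric(1),
                                     "nInformative"),
               wtByAbsence = vapply(allele, `[[`, logical(1), "wtByAbsence"),
               sizeFactor = sf, stringsAsFactors = FALSE)
  })
  writeTsv(geno, file.path(outDir, "sex_genotype.tsv"))

  deInput <- .stage("design", {
    grp <- ifelse(geno$alleleCall %in% c("missense", "deletion",
                                         "heterozygous"), "mut",
                  ifelse(geno$alleleCall == "WT", "WT", NA))
    use <- geno$sample[!is.na(grp)]
    list(samples = use,
         group = factor(grp[!is.na(grp)], levels = c("WT", "mut")))
  })
  report$genotyped <- list(used = length(deInput$samples),
                           droppedNoCall = length(kept) -
                             length(deInput$samples))

  geneDE <- .stage("gene-de", {
    cm <- counts[, deInput$samples, drop = FALSE]
    cd <- data.frame(group = deInput$group)
    res <- nbWaldTest(cm, ~ group, colData = cd, coef = "groupmut")
    ruvUsed <- FALSE
    if (config@batchStrength > 0) {
      ctrl <- tryCatch(selectControlGenes(res), error = function(e) character(0))
      k <- min(th$ruvK, ncol(cm) - 3L)
      if (length(ctrl) >= 5L && k >= 1L) {
        W <- ruvW(ruvFactors(cm, ctrl, k = k))
        cd <- cbind(cd, as.data.frame(W))
        form <- stats::as.formula(paste("~", paste(colnames(W), collapse = " + "),
                                        "+ group"))
        res <- nbWaldTest(cm, form, colData = cd, coef = "groupmut")
        ruvUsed <- TRUE
      }
    }
    res <- independentFiltering(res, alpha = th$filterAlpha)
    list(res = res, ruvUsed = ruvUsed)
  })
  geneTab <- as.data.frame(deTable(geneDE$res))
  writeTsv(cbind(feature = rownames(geneTab), geneTab),
           file.path(outDir, "gene_de.tsv"))
  report$geneDE <- list(
    tested = sum(!is.na(geneTab$pvalue)),
    degAtAlpha = sum(geneTab$padj < th$degAlpha, na.rm = TRUE),
    ruvUsed = geneDE$ruvUsed)

  te <- .stage("te-quant", {
    rct <- .teQuantStage(config, ann, deInput$samples,
                         isMutant = deInput$group == "mut",
                         teEffectLog2FC = teEffectLog2FC, outDir = outDir)
    fpkName <- dnaContamination(fpkmByRepName(rct), madK = th$madK)
    fpkFam <- fpkmByRepFamily(rct)
    writeRepeatTables(rct, fpkName, file.path(outDir, "te_repname"))
    writeCountsTsv(round(fpkmValues(fpkFam), 6),
                   file.path(outDir, "te_family_fpkm.tsv"))
    list(rct = rct, fpkName = fpkName, fpkFam = fpkFam)
  })
  report$teQuant <- list(
    fragmentsCounted = sum(repeatCounts(te$rct)),
    ambiguous = sum(te$rct@ambiguousFragments),
    dnaFlagged = sum(attr(te$fpkName, "flagged")))

  teDE <- .stage("te-de", {
    cm <- repeatCounts(te$rct)
    cd <- data.frame(dnaFpkm = as.numeric(dnaFpkm(te$fpkName)),
                     group = deInput$group)
    res <- nbWaldTest(cm, ~ dnaFpkm + group, colData = cd, coef = "groupmut")
    res <- independentFiltering(res, alpha = th$filterAlpha)
    ## family level: summed member counts, same covariate
    fam <- te$rct@nameToFamily[rownames(cm)]
    famCounts <- rowsum(cm, fam)
    famRes <- nbWaldTest(famCounts, ~ dnaFpkm + group, colData = cd,
                         coef = "groupmut")
    list(res = res, famRes = famRes)
  })
  teTab <- as.data.frame(deTable(teDE$res))
  famTab <- as.data.frame(deTable(teDE$famRes))
  writeTsv(cbind(repName = rownames(teTab), teTab),
           file.path(outDir, "te_de.tsv"))
  writeTsv(cbind(repFamily = rownames(famTab), famTab),
           file.path(outDir, "te_family_de.tsv"))
  report$teDE <- list(
    significantRepNames = rownames(teTab)[!is.na(teTab$padj) &
                                            teTab$padj < th$teAlpha],
    significantFamilies = rownames(famTab)[!is.na(famTab$padj) &
                                             famTab$padj < th$teAlpha])

  enr <- .stage("enrichment", {
    ranked <- rankBySignedSignificance(geneDE$res)
    if (is.null(geneSets)) {
      planted <- names(config@effectLog2FC)
      geneSets <- makeToyGeneSets(rownames(counts),
                                  planted = if (length(planted) >= 10) planted,
                                  seed = config@seed)
    }
    gsea <- runGSEA(ranked, geneSets, nPerm = nPerm, seed = config@seed)
    degs <- rownames(geneTab)[!is.na(geneTab$padj) &
                                geneTab$padj < th$degAlpha]
    universe <- rownames(geneTab)[!is.na(geneTab$pvalue)]
    ora <- if (length(degs)) hypergeomORA(degs, universe, geneSets) else NULL
    list(gsea = gsea, ora = ora, ranked = ranked, degs = degs)
  })
  writeTsv(enr$gsea, file.path(outDir, "gsea.tsv"))
  if (!is.null(enr$ora)) writeTsv(enr$ora, file.path(outDir, "ora.tsv"))

  delay <- .stage("dev-delay", {
    reps <- rownames(teTab)
    stage <- simulateStageTrajectory(reps, seed = config@seed)
    e35 <- blastocystStageValue(stage)
    lfcTe <- log2((stage[, "E3.5_TE"] + 1) / (stage[, "8cell"] + 1))
    lfcIcm <- log2((stage[, "E3.5_ICM"] + 1) / (stage[, "8cell"] + 1))
    dev <- weightedDevLog2FC(lfcTe, lfcIcm)
    sig <- !is.na(teTab$padj) & teTab$padj < th$teAlpha
    corr <- tryCatch(delayCorrelation(teTab$log2FoldChange, dev, sig),
                     error = function(e) list(rAll = NA, rSignificant = NA))
    ci <- bootstrapMeanCI(e35, seed = config@seed)
    df <- data.frame(repName = reps, devLog2FC = dev, e35TPM = e35,
                     mutantLog2FC = teTab$log2FoldChange, significant = sig)
    writeTsv(df, file.path(outDir, "dev_delay.tsv"))
    list(rAll = corr$rAll, rSignificant = corr$rSignificant,
         e35MeanCI = as.list(ci))
  })
  report$devDelay <- delay

  report$hash <- reportHash(outDir)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

## determinism hash: md5 of the sorted (name, md5) pairs of all TSV outputs
reportHash <- function(outDir) {
  files <- sort(list.files(outDir, pattern = "\\.tsv$", full.names = TRUE))
  sums <- tools::md5sum(files)
  tmp <- tempfile()
  writeLines(paste(basename(names(sums)), sums), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the bulk (placenta-style) workflow on synthetic data
#'
#' Sex-stratified genotype differential expression (separate analyses for
#' female and male samples), a sex-contrast analysis recovering sex-linked
#' dosage genes, marker-set enrichment through the GSEA interface, and
#' repeat quantification with the DNA-contamination covariate. Validates
#' that the sample metadata carries sex and genotype before any
#' computation.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param outDir output directory.
#' @param colData optional data.frame with sex and genotype per sample;
#'   default: balanced 2 genotypes x 2 sexes with
#'   \code{2 x nSamplesPerGroup} samples per sex.
#' @param sexEffectLog2FC named numeric of planted sex-linked dosage
#'   effects (positive = higher in females).
#' @param teEffectLog2FC planted repFamily effects in mutants.
#' @param thresholds,geneSets,nPerm as in \code{\link{runEmbryoWorkflow}}.
#' @return (invisibly) the report list.
#' @export
runBulkWorkflow <- function(config, outDir, colData = NULL,
                            sexEffectLog2FC = numeric(0),
                            teEffectLog2FC = numeric(0),
                            thresholds = defaultThresholds(),
                            geneSets = NULL, nPerm = 1000L) {
  th <- utils::modifyList(defaultThresholds(), thresholds)
  if (!is.null(colData) &&
      !all(c("sex", "genotype") %in% colnames(colData)))
    stop("sample metadata must include 'sex' and 'genotype'")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(workflow = "bulk", seed = config@seed)

  if (is.null(colData)) {
    n <- config@nSamplesPerGroup
    colData <- expand.grid(genotype = c("WT", "mut"),
                           sex = c("male", "female"),
                           rep = seq_len(n))[, 1:2]
    colData[] <- lapply(colData, as.character)
  }
  sim <- .stage("bulk-simulation", {
    design <- data.frame(group = factor(colData$genotype,
                                        levels = c("WT", "mut")),
                         sex = colData$sex)
    simulateCounts(config, design = design,
                   sexEffectLog2FC = sexEffectLog2FC,
                   streamLabel = "bulk-counts")
  })
  counts <- SummarizedExperiment::assay(sim, "counts")

  strat <- .stage("sex-stratified-de", {
    lapply(setNames(unique(colData$sex), unique(colData$sex)), function(sx) {
      idx <- colData$sex == sx
      cm <- counts[, idx, drop = FALSE]
      cd <- data.frame(group = factor(colData$genotype[idx],
                                      levels = c("WT", "mut")))
      independentFiltering(nbWaldTest(cm, ~ group, colData = cd,
                                      coef = "groupmut"),
                           alpha = th$filterAlpha)
    })
  })
  for (sx in names(strat)) {
    tab <- as.data.frame(deTable(strat[[sx]]))
    writeTsv(cbind(feature = rownames(tab), tab),
             file.path(outDir, paste0("gene_de_", sx, ".tsv")))
  }
  report$stratifiedDE <- lapply(strat, function(res) {
    tab <- deTable(res)
    sum(tab$padj < th$degAlpha, na.rm = TRUE)
  })

  sexDE <- .stage("sex-contrast-de", {
    cd <- data.frame(sex = factor(colData$sex, levels = c("male", "female")))
    independentFiltering(nbWaldTest(counts, ~ sex, colData = cd,
                                    coef = "sexfemale"),
                         alpha = th$filterAlpha)
  })
  sexTab <- as.data.frame(deTable(sexDE))
  writeTsv(cbind(feature = rownames(sexTab), sexTab),
           file.path(outDir, "gene_de_sex_contrast.tsv"))
  report$sexContrastDEGs <- sum(sexTab$padj < th$degAlpha, na.rm = TRUE)

  enr <- .stage("marker-enrichment", {
    ranked <- rankBySignedSignificance(sexDE)
    if (is.null(geneSets))
      geneSets <- makeToyGeneSets(rownames(counts),
                                  planted = names(sexEffectLog2FC),
                                  seed = config@seed)
    runGSEA(ranked, geneSets, nPerm = nPerm, seed = config@seed)
  })
  writeTsv(enr, file.path(outDir, "marker_gsea.tsv"))

  te <- .stage("te-quant", {
    ann <- makeToyAnnotation(config)
    sampleIds <- paste0("bulk", seq_len(nrow(colData)))
    rct <- .teQuantStage(config, ann, sampleIds,
                         isMutant = colData$genotype != "WT",
                         teEffectLog2FC = teEffectLog2FC, outDir = outDir)
    fpk <- dnaContamination(fpkmByRepName(rct), madK = th$madK)
    writeRepeatTables(rct, fpk, file.path(outDir, "te_repname"))
    cd <- data.frame(dnaFpkm = as.numeric(dnaFpkm(fpk)),
                     group = factor(colData$genotype, levels = c("WT", "mut")))
    res <- independentFiltering(
      nbWaldTest(repeatCounts(rct), ~ dnaFpkm + group, colData = cd,
                 coef = "groupmut"), alpha = th$filterAlpha)
    tab <- as.data.frame(deTable(res))
    writeTsv(cbind(repName = rownames(tab), tab),
             file.path(outDir, "te_de.tsv"))
    rownames(tab)[!is.na(tab$padj) & tab$padj < th$teAlpha]
  })
  report$teDE <- list(significantRepNames = te)

  report$hash <- reportHash(outDir)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
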