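smallCatalog <- function() {
  data.frame(repName = c("IAPEz-int", "Tigger1"),
             repFamily = c("ERVK", "TcMar-Tigger"),
             repClass = c("LTR", "DNA"))
}

test_that("minimal annotation placement labels disjoint elements", {
  cfg <- SimConfig(seed = 1, nChromosomes = 1, chromLengthBp = 50000,
                   nRepeatElements = 2, repnameCatalog = smallCatalog(),
                   nGenes = 3)
  ann <- makeToyAnnotation(cfg)
  expect_length(ann$repeats, 2)
  expect_setequal(ann$repeats$repName, c("IAPEz-int", "Tigger1"))
  hits <- GenomicRanges::findOverlaps(ann$repeats, ignore.strand = TRUE,
                                      drop.self = TRUE)
  expect_length(hits, 0)
  # genes and repeats do not overlap either
  expect_length(GenomicRanges::findOverlaps(ann$repeats, ann$genes,
                                            ignore.strand = TRUE), 0)
  # designated special genes exist
  expect_setequal(
    unique(ann$genes$geneType),
    c("standard", "rdna", "y_linked", "mito"))
})

test_that("annotation generation is deterministic under the seed", {
  cfg <- SimConfig(seed = 42, nGenes = 10, nRepeatElements = 20)
  a1 <- makeToyAnnotation(cfg)
  a2 <- makeToyAnnotation(cfg)
  expect_identical(as.data.frame(a1$repeats), as.data.frame(a2$repeats))
  expect_identical(as.data.frame(a1$genes), as.data.frame(a2$genes))
  expect_identical(as.character(a1$genome), as.character(a2$genome))
})

test_that("impossible placements raise a sizing error", {
  cfg <- SimConfig(seed = 1, nChromosomes = 1, chromLengthBp = 10000,
                   nRepeatElements = 100, repnameCatalog = smallCatalog(),
                   nGenes = 2)
  expect_error(makeToyAnnotation(cfg), "too short")
})

test_that("degenerate rates concentrate fragments on the active repeat", {
  cfg <- SimConfig(seed = 3, nChromosomes = 1, chromLengthBp = 100000,
                   nRepeatElements = 6, repnameCatalog = smallCatalog(),
                   nGenes = 3, meanDepthFragments = 500,
                   dnaContaminationFraction = 0)
  ann <- makeToyAnnotation(cfg)
  target <- ann$repeats$elementId[1]
  rates <- setNames(rep(0, length(ann$repeats) + length(ann$genes)),
                    c(ann$repeats$elementId, ann$genes$gene_id))
  rates[target] <- 1
  sim <- simulateFragments(cfg, ann, rates = rates, straddleFraction = 0)
  expect_true(all(sim$truth$provenance == paste0("repeat:", target)))
})

test_that("contaminant fragment count falls in the binomial 99% interval", {
  cfg <- SimConfig(seed = 7, meanDepthFragments = 10000,
                   dnaContaminationFraction = 0.2)
  ann <- makeToyAnnotation(cfg)
  sim <- simulateFragments(cfg, ann)
  nContam <- sum(sim$truth$provenance == "dna_contaminant")
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.2)
  expect_gte(nContam, bounds[1])
  expect_lte(nContam, bounds[2])
  # provenance labels partition the fragment set
  expect_identical(nrow(sim$truth), length(sim$fragments))
  expect_false(anyNA(sim$truth$provenance))
  expect_false(anyDuplicated(sim$truth$qname) > 0)
})

test_that("pure-WT allele mixture yields only WT-matching codon reads", {
  cfg <- SimConfig(seed = 5)
  ann <- makeToyAnnotation(cfg)
  sim <- simulateFragments(cfg, ann, alleleFractions = c(1, 0, 0),
                           nLocusReads = 25)
  tpl <- alleleTemplates(ann)
  expect_true(all(vapply(sim$locusReads$seq, grepl, logical(1),
                         x = tpl[["WT"]], fixed = TRUE)))
  expect_true(all(sim$locusReads$cigar == "50M"))
})

test_that("simulated counts match the NB mean-variance relation", {
  # one long row of iid draws per gene: equal size factors, no batch
  cfg <- SimConfig(seed = 9, nGenes = 4, nSamplesPerGroup = 3000,
                   nbDispersion = 0.1)
  se <- simulateCounts(cfg, sizeFactorRange = c(1, 1))
  counts <- SummarizedExperiment::assay(se)
  base <- SummarizedExperiment::rowData(se)$baselineMean
  for (g in seq_len(nrow(counts))) {
    x <- counts[g, ]
    mu <- base[g]
    target <- mu + 0.1 * mu^2
    seVar <- sd((x - mean(x))^2) / sqrt(length(x))
    expect_lt(abs(var(x) - target), 3 * seVar + 0.05 * target)
    seMean <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - mu), 4 * seMean)
  }
})

test_that("the dispersion-to-zero limit is Poisson", {
  cfg <- SimConfig(seed = 11, nGenes = 2, nSamplesPerGroup = 5000,
                   nbDispersion = 1e-12)
  se <- simulateCounts(cfg, sizeFactorRange = c(1, 1))
  counts <- SummarizedExperiment::assay(se)
  ratio <- apply(counts, 1, var) / rowMeans(counts)
  expect_true(all(abs(ratio - 1) < 0.1))
})

test_that("null count simulation has no group structure", {
  cfg <- SimConfig(seed = 13, nGenes = 200, nSamplesPerGroup = 8)
  se <- simulateCounts(cfg)
  expect_true(all(SummarizedExperiment::rowData(se)$trueLog2FC == 0))
})

test_that("embryo cohort encodes sexes, depth flags and is deterministic", {
  cfg <- SimConfig(seed = 21, nGenes = 20, nSamplesPerGroup = 2)
  coh <- simulateEmbryoCohort(cfg, sexes = c("male", "male", "female",
                                             "female"), yGeneRate = 50,
                              totalReads = c(2e6, 5e5, 2e6, 2e6))
  expect_identical(sum(coh$truth$sex == "male"), 2L)
  expect_identical(coh$truth$belowDepth, c(FALSE, TRUE, FALSE, FALSE))
  counts <- SummarizedExperiment::assay(coh$se)
  gt <- coh$annotation$genes$geneType
  ySum <- colSums(counts[gt == "y_linked", ])
  expect_true(all(ySum[coh$truth$sex == "male"] > 10))
  expect_true(all(ySum[coh$truth$sex == "female"] == 0))
  coh2 <- simulateEmbryoCohort(cfg, sexes = c("male", "male", "female",
                                              "female"), yGeneRate = 50,
                               totalReads = c(2e6, 5e5, 2e6, 2e6))
  expect_identical(SummarizedExperiment::assay(coh2$se), counts)
})

test_that("SimConfig validity rejects bad fractions and dispersion", {
  expect_error(SimConfig(nbDispersion = 0), "nbDispersion")
  expect_error(SimConfig(dnaContaminationFraction = 1.2), "\\[0,1\\]")
  am <- matrix(c(0.5, 0.2, 0.2), 1, dimnames = list(NULL, c("wt", "missense", "deletion")))
  expect_error(SimConfig(alleleMix = am), "sum to 1")
})

test_that("config YAML round trip preserves the configuration", {
  am <- matrix(c(1, 0, 0, 0, 0, 1), 2, byrow = TRUE,
               dimnames = list(NULL, c("wt", "missense", "deletion")))
  cfg <- SimConfig(seed = 4, nGenes = 11, effectLog2FC = c(gene3 = 1),
                   alleleMix = am)
  path <- tempfile(fileext = ".yaml")
  writeSimConfigYaml(cfg, path)
  cfg2 <- readSimConfigYaml(path)
  expect_equal(cfg2@seed, cfg@seed)
  expect_equal(cfg2@effectLog2FC, cfg@effectLog2FC)
  expect_equal(cfg2@alleleMix, cfg@alleleMix, ignore_attr = TRUE)
  # and identical configs give identical outputs
  expect_identical(
    SummarizedExperiment::assay(simulateCounts(cfg2)),
    SummarizedExperiment::assay(simulateCounts(cfg)))
})
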