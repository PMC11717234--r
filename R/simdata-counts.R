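#' Simulate a negative-binomial count matrix with known effects
#'
#' Counts are drawn feature-by-sample from
#' NB(mean = baseline x 2^(log2FC x group) x 2^(batch term) x size factor,
#' dispersion = \code{nbDispersion}). The batch term is
#' \code{batchStrength x batchValue(sample) x loading(feature)} with
#' per-sample batch values standard normal and per-feature loadings uniform
#' on [0.5, 1.5], so a single latent factor drives the unwanted variation.
#' True effects, batch values and size factors are recorded.
#'
#' @param config a \linkS4class{SimConfig}; \code{effectLog2FC} names the
#'   perturbed features (all others are null).
#' @param design optional data.frame with a \code{group} factor (two or more
#'   levels) and optionally \code{batch} numeric; default: two groups of
#'   \code{nSamplesPerGroup}.
#' @param featureIds feature names; default \code{gene1..geneN}.
#' @param baselineMeans named baseline means; default log-normal around 100.
#' @param sizeFactorRange range for true size factors; use \code{c(1, 1)}
#'   for equal depths.
#' @param sexEffectLog2FC named numeric: additional log2 effect applied to
#'   the named features in samples whose \code{design$sex == "female"}
#'   (sex-linked dosage structure); default none.
#' @param streamLabel RNG stream label (vary to get independent replicates
#'   from one config).
#' @return \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{counts}, colData (group, batchValue, sizeFactorTrue), rowData
#'   (baselineMean, trueLog2FC, batchLoading).
#' @examples
#' se <- simulateCounts(SimConfig(seed = 1, nGenes = 50))
#' dim(se)
#' @export
simulateCounts <- function(config, design = NULL, featureIds = NULL,
                           baselineMeans = NULL,
                           sizeFactorRange = c(0.7, 1.4),
                           sexEffectLog2FC = numeric(0),
                           streamLabel = "counts") {
  stopifnot(is(config, "SimConfig"))
  if (config@nbDispersion <= 0) stop("nbDispersion must be > 0")
  if (is.null(design)) {
    n <- config@nSamplesPerGroup
    if (n < 2L) stop("need >= 2 samples per group")
    design <- data.frame(group = factor(rep(c("ctrl", "mut"), each = n)))
  }
  if (!is.factor(design$group)) design$group <- factor(design$group)
  if (any(table(design$group) < 2L)) stop("need >= 2 samples per group")
  nS <- nrow(design)
  if (is.null(featureIds)) featureIds <- paste0("gene", seq_len(config@nGenes))
  nG <- length(featureIds)

  withStream(config@seed, streamLabel, {
    if (is.null(baselineMeans)) {
      baselineMeans <- setNames(exp(rnorm(nG, log(100), 1)), featureIds)
    } else {
      baselineMeans <- baselineMeans[featureIds]
    }
    lfc <- setNames(numeric(nG), featureIds)
    known <- intersect(names(config@effectLog2FC), featureIds)
    lfc[known] <- config@effectLog2FC[known]

    batchValue <- if (!is.null(design$batch)) as.numeric(design$batch)
                  else if (config@batchStrength > 0) rnorm(nS) else numeric(nS)
    loading <- runif(nG, 0.5, 1.5)
    sf <- runif(nS, sizeFactorRange[1], sizeFactorRange[2])

    groupInd <- as.integer(design$group) - 1L  # 0 = reference level
    mu <- outer(baselineMeans, rep(1, nS)) *
      2^(outer(lfc, groupInd)) *
      2^(config@batchStrength * outer(loading, batchValue)) *
      rep(sf, each = nG)
    if (length(sexEffectLog2FC) && !is.null(design$sex)) {
      sexLfc <- setNames(numeric(nG), featureIds)
      known2 <- intersect(names(sexEffectLog2FC), featureIds)
      sexLfc[known2] <- sexEffectLog2FC[known2]
      femInd <- as.integer(design$sex == "female")
      mu <- mu * 2^(outer(sexLfc, femInd))
      lfc <- lfc  # condition effects unchanged
    }
    alpha <- config@nbDispersion
    counts <- if (alpha < 1e-10) {
      matrix(rpois(nG * nS, lambda = mu), nrow = nG)
    } else {
      matrix(rnbinom(nG * nS, mu = mu, size = 1 / alpha), nrow = nG)
    }
    dimnames(counts) <- list(featureIds, paste0("s", seq_len(nS)))

    cd <- S4Vectors::DataFrame(group = design$group, batchValue = batchValue,
                               sizeFactorTrue = sf,
                               row.names = colnames(counts))
    if (!is.null(design$sex)) cd$sex <- design$sex
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      colData = cd,
      rowData = S4Vectors::DataFrame(baselineMean = baselineMeans,
                                     trueLog2FC = lfc,
                                     batchLoading = loading,
                                     row.names = featureIds),
      metadata = list(nbDispersion = alpha, seed = config@seed,
                      streamLabel = streamLabel))
  })
}

#' Synthetic preimplantation stage-trajectory table
#'
#' A stand-in for public stage-resolved expression data: per-feature TPM
#' across preimplantation stages (zygote to E3.5 ICM and trophectoderm),
#' generated as a smooth log-normal random walk across stages so neighbour
#' stages are correlated.
#'
#' @param featureIds feature names.
#' @param seed integer seed.
#' @param stages stage labels; must keep the 8-cell and both E3.5 columns
#'   for the developmental-delay constructions.
#' @return numeric matrix, features x stages (TPM scale).
#' @export
simulateStageTrajectory <- function(featureIds, seed = 1L,
                                    stages = c("zygote", "2cell", "4cell",
                                               "8cell", "morula",
                                               "E3.5_ICM", "E3.5_TE")) {
  withr::with_seed(streamSeed(seed, "stage-trajectory"), {
    nF <- length(featureIds); nS <- length(stages)
    logtpm <- matrix(0, nF, nS, dimnames = list(featureIds, stages))
    logtpm[, 1] <- rnorm(nF, log(50), 1.2)
    for (j in 2:nS) logtpm[, j] <- logtpm[, j - 1] + rnorm(nF, 0, 0.8)
    tpm <- exp(logtpm)
    sweep(tpm, 2, colSums(tpm), "/") * 1e6
  })
}

#' Toy gene sets in GMT-like form
#'
#' Random gene sets over the supplied universe, optionally with one planted
#' set enriched in a given id vector, for exercising the enrichment stack.
#'
#' @param universe feature ids.
#' @param nSets number of random sets.
#' @param setSize members per set.
#' @param planted optional character vector of ids forming an extra set
#'   named \code{"planted"}.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
makeToyGeneSets <- function(universe, nSets = 10L, setSize = 20L,
                            planted = NULL, seed = 1L) {
  withr::with_seed(streamSeed(seed, "genesets"), {
    sets <- lapply(seq_len(nSets), function(i)
      sample(universe, min(setSize, length(universe))))
    names(sets) <- paste0("set", seq_len(nSets))
    if (!is.null(planted)) sets$planted <- unique(planted)
    sets
  })
}
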