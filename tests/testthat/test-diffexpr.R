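test_that("median-of-ratios size factors match hand-computed values", {
  m <- cbind(s1 = c(10, 100, 50), s2 = c(20, 200, 100))
  expect_equal(unname(sizeFactorsMedianRatios(m)),
               c(sqrt(1 / 2), sqrt(2)))
  # identical columns: all ones
  m2 <- cbind(a = c(5, 7), b = c(5, 7), c = c(5, 7))
  expect_equal(unname(sizeFactorsMedianRatios(m2)), rep(1, 3))
  # single sample: 1 by convention
  expect_equal(unname(sizeFactorsMedianRatios(matrix(1:3, ncol = 1))), 1)
  # no all-positive feature
  expect_error(sizeFactorsMedianRatios(cbind(c(0, 1), c(1, 0))),
               "pseudo-reference")
})

test_that("normalization absorbs per-sample scaling exactly", {
  set.seed(1)
  m <- matrix(rnbinom(200, mu = 50, size = 5), 20, 10)
  m[m == 0] <- 1
  nc1 <- normalizedCounts(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 5
  nc2 <- normalizedCounts(m2)
  # the scaled sample is absorbed: normalized profiles agree up to one
  # global constant (the geometric-mean reference shifts by 5^(1/n))
  ratio <- nc2 / nc1
  expect_lt(diff(range(ratio)), 1e-12)
  expect_equal(ratio[1, 1], 5^(1 / 10), tolerance = 1e-12)
})

test_that("TPM follows the length-first normalization", {
  tpm <- computeTPM(c(10, 10), c(1, 2))
  expect_equal(tpm[, 1], c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(sum(tpm), 1e6)
  # one nonzero feature takes the full million
  expect_equal(computeTPM(c(0, 7), c(1, 3))[2, 1], 1e6)
  # scale invariance
  expect_equal(computeTPM(c(50, 50), c(1, 2)), computeTPM(c(10, 10), c(1, 2)))
  expect_warning(z <- computeTPM(c(0, 0), c(1, 2)), "all-zero")
  expect_true(all(z == 0))
  expect_error(computeTPM(c(1, 2), c(0, 1)), "> 0")
})

test_that("BH adjustment is step-up with NA propagation", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(c(1, 1)), c(1, 1))
  p <- c(0.04, NA, 0.01, 0.5)
  adj <- bhAdjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[!is.na(p)], bhOracle(p[!is.na(p)]))
  # order invariance and random-oracle agreement
  set.seed(2)
  for (i in 1:5) {
    q <- runif(50)
    expect_equal(bhAdjust(q), bhOracle(q))
    perm <- sample(50)
    expect_equal(bhAdjust(q[perm]), bhAdjust(q)[perm])
  }
})

test_that("Wald test is exact under symmetry and matches the mean-ratio MLE", {
  cd <- data.frame(group = factor(rep(c("a", "b"), each = 10)))
  y <- c(5, 9, 13, 7, 8, 10, 11, 6, 9, 12)
  res <- deTable(nbWaldTest(matrix(rep(y, 2), 1,
                                   dimnames = list("g1", NULL)),
                            ~ group, colData = cd,
                            sizeFactors = rep(1, 20)))
  expect_equal(res$log2FoldChange, 0, tolerance = 1e-8)
  expect_equal(res$pvalue, 1, tolerance = 1e-8)
  # low-dispersion limit: estimate equals log2 of the group-mean ratio
  set.seed(4)
  y1 <- rpois(10, 1e5); y2 <- rpois(10, 2e5)
  res2 <- deTable(nbWaldTest(rbind(g1 = c(y1, y2),
                                   g2 = c(rpois(10, 1e5), rpois(10, 1e5)),
                                   g3 = c(rpois(10, 5e4), rpois(10, 5e4))),
                             ~ group, colData = cd,
                             sizeFactors = rep(1, 20)))
  expect_equal(res2$log2FoldChange[1], log2(mean(y2) / mean(y1)),
               tolerance = 1e-4)
  expect_equal(res2$log2FoldChange[1], 1, tolerance = 0.01)
})

test_that("null p-values are calibrated and near-uniform", {
  set.seed(17)
  G <- 1000
  counts <- matrix(rnbinom(G * 20, mu = 100, size = 10), G, 20,
                   dimnames = list(paste0("g", 1:G), NULL))
  cd <- data.frame(group = factor(rep(c("a", "b"), each = 10)))
  res <- deTable(nbWaldTest(counts, ~ group, colData = cd))
  p <- res$pvalue[!is.na(res$pvalue)]
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.08)
  # ECDF within a 5% Kolmogorov band of uniform
  ks <- max(abs(sort(p) - seq_along(p) / length(p)))
  expect_lt(ks, 0.05)
})

test_that("independent filtering maximizes rejections over the scan grid", {
  mkDE <- function(baseMean, pvalue) {
    new("DEResult",
        results = S4Vectors::DataFrame(
          baseMean = baseMean, log2FoldChange = 0, lfcSE = 1, stat = 0,
          pvalue = pvalue, padj = bhAdjust(pvalue),
          filtered = rep(FALSE, length(pvalue)),
          row.names = paste0("g", seq_along(pvalue))),
        coefName = "x", dispersions = numeric(0))
  }
  # identical baseMean: nothing filtered
  resEq <- independentFiltering(mkDE(rep(10, 20), runif(20)))
  expect_false(any(deTable(resEq)$filtered))
  expect_equal(attr(resEq, "filterThreshold"), 10)
  # 50 uninformative low-mean features hide one borderline discovery
  set.seed(8)
  pLow <- runif(50, 0.2, 1)
  pHigh <- c(0.0009, rep(0.6, 9))  # 0.0009 * 10 / 1 = 0.009 < alpha only
                                   # after filtering (n 60 -> 10)
  de <- mkDE(c(rep(0.5, 50), rep(100, 10)), c(pLow, pHigh))
  expect_identical(sum(deTable(de)$padj < 0.05, na.rm = TRUE), 0L)
  filt <- independentFiltering(de, alpha = 0.05)
  tab <- deTable(filt)
  expect_identical(sum(tab$filtered), 50L)
  expect_identical(sum(tab$padj < 0.05, na.rm = TRUE), 1L)
  expect_true(all(is.na(tab$padj[tab$filtered])))
  # exhaustive scan oracle: the chosen threshold attains the max rejections
  thr <- quantile(c(rep(0.5, 50), rep(100, 10)), seq(0, 0.95, 0.01),
                  type = 7)
  rej <- vapply(thr, function(t) {
    keep <- c(rep(0.5, 50), rep(100, 10)) >= t
    sum(bhOracle(c(pLow, pHigh)[keep]) < 0.05)
  }, numeric(1))
  expect_identical(sum(tab$padj < 0.05, na.rm = TRUE), as.integer(max(rej)))
  # alpha = 1: every feature rejected at every threshold, lowest chosen
  resA <- independentFiltering(mkDE(1:20, runif(20)), alpha = 1)
  expect_false(any(deTable(resA)$filtered))
})

test_that("control-gene selection intersects the three criteria", {
  mk <- function(bm, padj, lfc) {
    new("DEResult",
        results = S4Vectors::DataFrame(
          baseMean = bm, log2FoldChange = lfc, lfcSE = 1, stat = 0,
          pvalue = padj, padj = padj, filtered = rep(FALSE, length(bm)),
          row.names = paste0("g", seq_along(bm))),
        coefName = "x", dispersions = numeric(0))
  }
  resA <- mk(c(150, 150, 150, 50), c(0.9, 0.5, 0.9, 0.9),
             c(0.01, 0.01, -0.04, 0.01))
  resB <- mk(c(150, 150, 150, 150), c(0.9, 0.9, 0.95, 0.9),
             c(0.02, 0.02, 0.03, 0.02))
  ctrl <- selectControlGenes(list(resA, resB))
  expect_setequal(ctrl, c("g1", "g3"))  # g2 fails padj in A, g4 fails mean
  # the |log2FC| reading admits -0.04; the signed reading admits more
  expect_true("g3" %in% ctrl)
  expect_error(selectControlGenes(list(mk(10, 0.1, 2))), "relaxing")
})

test_that("RUV factors recover a planted batch factor and its symmetries", {
  cfg <- SimConfig(seed = 23, nGenes = 300, batchStrength = 0.6)
  se <- simulateCounts(cfg)
  cm <- SummarizedExperiment::assay(se)
  truthB <- SummarizedExperiment::colData(se)$batchValue
  rv <- ruvFactors(cm, rownames(cm)[1:80], k = 4)
  W <- ruvW(rv)
  expect_gt(abs(cor(W[, 1], truthB)), 0.9)
  # columns orthogonal (validity), sign convention: max-|entry| positive
  expect_true(all(vapply(seq_len(ncol(W)), function(j)
    W[which.max(abs(W[, j])), j] >= 0, logical(1))))
  # permuting samples permutes rows identically
  perm <- sample(ncol(cm))
  Wp <- ruvW(ruvFactors(cm[, perm], rownames(cm)[1:80], k = 4))
  expect_equal(abs(Wp[, 1]), abs(W[perm, 1]), tolerance = 1e-6)
  # constant controls: degenerate zero W with warning
  cmConst <- cm
  cmConst[1:80, ] <- 7L
  expect_warning(rv0 <- ruvFactors(cmConst, rownames(cm)[1:80], k = 2,
                                   sizeFactors = rep(1, ncol(cm))),
                 "constant")
  expect_true(all(ruvW(rv0) == 0))
  expect_error(ruvFactors(cm, rownames(cm)[1:10], k = ncol(cm)), "smaller")
})

test_that("PCA embedding filters, selects by variance and separates groups", {
  set.seed(12)
  m <- matrix(rnbinom(600, mu = 100, size = 10), 30, 20,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
  # duplicated samples land on identical coordinates
  m[, 2] <- m[, 1]
  p <- pcaEmbed(m, nTop = 20, minMean = 1)
  expect_equal(p$x[1, ], p$x[2, ], tolerance = 1e-9, ignore_attr = TRUE)
  expect_lte(sum(p$varExplained), 1 + 1e-9)
  # planted two-group shift separates on PC1
  cfg <- SimConfig(seed = 29, nGenes = 400, nSamplesPerGroup = 8,
                   effectLog2FC = setNames(rep(1.5, 200),
                                           paste0("gene", 1:200)))
  se <- simulateCounts(cfg)
  emb <- pcaEmbed(SummarizedExperiment::assay(se), nTop = 300, minMean = 5)
  grp <- SummarizedExperiment::colData(se)$group
  expect_gt(silhouette1d(emb$x[, 1], grp), 0.8)
  # more components than features: reduced with warning
  expect_warning(pcaEmbed(m[1:5, ], nTop = 1000, minMean = 0), "using all")
})

test_that("the engine agrees with an established NB GLM implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(41)
  G <- 60
  lfc <- c(rep(0, 40), rep(1, 20))
  mu <- matrix(120, G, 12)
  mu[lfc == 1, 7:12] <- 240
  counts <- matrix(rnbinom(G * 12, mu = mu, size = 1 / 0.05), G, 12,
                   dimnames = list(paste0("g", 1:G), paste0("s", 1:12)))
  cd <- data.frame(group = factor(rep(c("a", "b"), each = 6)))
  mine <- deTable(nbWaldTest(counts, ~ group, colData = cd))
  dds <- DESeq2::DESeqDataSetFromMatrix(counts, cd, ~ group)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, independentFiltering = FALSE)
  expect_gt(cor(mine$log2FoldChange, ref$log2FoldChange), 0.99)
  expect_gt(cor(-log10(mine$pvalue + 1e-300),
                -log10(ref$pvalue + 1e-300)), 0.9)
})
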