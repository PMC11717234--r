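rmFixture <- function(path, rows) {
  hdr <- c("header1", "header2", "")
  writeLines(c(hdr, rows), path)
  path
}

test_that("RepeatMasker loading honours the simple-repeat exclusion", {
  path <- tempfile(fileext = ".out")
  rmFixture(path, c(
    "1000 1.0 0.0 0.0 chr1 101 200 (0) + IAPEz-int LTR/ERVK 1 100 (0) 1",
    "1000 1.0 0.0 0.0 chr1 301 400 (0) C (CA)n Simple_repeat 1 100 (0) 2",
    "1000 1.0 0.0 0.0 chr2 501 900 (0) + Tigger1 DNA/TcMar-Tigger 1 400 (0) 3"))
  withExcl <- loadRepeatAnnotation(path, excludeSimple = TRUE)
  expect_length(withExcl, 2)
  expect_false("Simple_repeat" %in% withExcl$repClass)
  noExcl <- loadRepeatAnnotation(path, excludeSimple = FALSE)
  expect_length(noExcl, 3)
  # class/family split and strand decoding
  expect_identical(withExcl$repFamily, c("ERVK", "TcMar-Tigger"))
  expect_identical(as.character(BiocGenerics::strand(noExcl))[2], "-")
})

test_that("malformed rows and inconsistent families are rejected", {
  bad <- tempfile(fileext = ".out")
  rmFixture(bad, "1000 1.0 0.0 0.0 chr1 200 101 (0) + IAPEz-int LTR/ERVK 1 100 (0) 1")
  expect_error(loadRepeatAnnotation(bad), "line")
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t50\tx\t0\t+\tx\tf\tLTR"), bed)
  expect_error(loadRepeatAnnotation(bed), "end <= start")
  incons <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tA\t0\t+\tA\tERVK\tLTR",
               "chr1\t300\t400\tA\t0\t+\tA\tERVL\tLTR"), incons)
  expect_error(loadRepeatAnnotation(incons), "inconsistent")
})

test_that("BED and RepeatMasker writers round-trip through the loader", {
  ann <- makeToyAnnotation(SimConfig(seed = 2, nRepeatElements = 12))
  reps <- ann$repeats
  bed <- tempfile(fileext = ".bed")
  writeRepeatBed(reps, bed)
  back <- loadRepeatAnnotation(bed, excludeSimple = FALSE)
  expect_identical(BiocGenerics::start(back), BiocGenerics::start(reps))
  expect_identical(BiocGenerics::end(back), BiocGenerics::end(reps))
  expect_identical(back$repName, reps$repName)
  out <- tempfile(fileext = ".out")
  writeRepeatMaskerOut(reps, out)
  back2 <- loadRepeatAnnotation(out, excludeSimple = FALSE)
  expect_identical(BiocGenerics::start(back2), BiocGenerics::start(reps))
  expect_identical(back2$repClass, reps$repClass)
})

test_that("fragment filter applies containment and gene exclusion", {
  reps <- gr0("chr1", 100, 200, repName = "R", repFamily = "F",
              repClass = "LTR")
  genes <- gr0("chr1", 300, 400, gene_id = "g1")
  # both mates contained, no gene overlap: kept
  fr <- PairedFragments(gr0("chr1", 110, 150), gr0("chr1", 160, 200))
  expect_length(filterRepeatFragments(fr, reps, genes), 1)
  # mate2 straddles the element boundary: dropped
  fr2 <- PairedFragments(gr0("chr1", 110, 150), gr0("chr1", 190, 230))
  expect_length(filterRepeatFragments(fr2, reps, genes), 0)
  # gene body overlap on mate2: dropped even though contained in a repeat
  genes2 <- gr0("chr1", 150, 400, gene_id = "g1")
  fr3 <- PairedFragments(gr0("chr1", 110, 140), gr0("chr1", 155, 195))
  expect_length(filterRepeatFragments(fr3, reps, genes2), 0)
})

test_that("filter agrees with the brute-force oracle and is stable", {
  for (seed in 1:5) {
    set.seed(seed)
    nR <- 20; nG <- 10; nF <- 300
    reps <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = sample(1:50000, nR),
                       width = sample(200:2000, nR, replace = TRUE)),
      repName = sample(c("A", "B", "C"), nR, replace = TRUE),
      repFamily = "F", repClass = "LTR")
    genes <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = sample(1:50000, nG),
                       width = sample(500:3000, nG, replace = TRUE)))
    s1 <- sample(1:52000, nF)
    s2 <- s1 + sample(50:300, nF, replace = TRUE)
    m1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s1, width = 50))
    m2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s2, width = 50))
    fr <- PairedFragments(m1, m2, names = paste0("f", seq_len(nF)))
    kept <- filterRepeatFragments(fr, reps, genes)
    oracle <- bruteFilterOracle(m1, m2, reps, genes)
    expect_identical(names(firstMate(kept)), paste0("f", which(oracle)))
    # order invariance
    perm <- sample(nF)
    keptPerm <- filterRepeatFragments(
      PairedFragments(m1[perm], m2[perm], names = paste0("f", perm)),
      reps, genes)
    expect_setequal(names(firstMate(keptPerm)), names(firstMate(kept)))
    # idempotence
    again <- filterRepeatFragments(kept, reps, genes)
    expect_identical(length(again), length(kept))
  }
})

test_that("counting assigns by repName and discards ambiguous pairs", {
  reps <- c(gr0("chr1", 0, 1000, repName = "IAPLTR2_Mm", repFamily = "ERVK",
                repClass = "LTR"),
            gr0("chr1", 2000, 3000, repName = "L1MdTf_I", repFamily = "L1",
                repClass = "LINE"),
            gr0("chr1", 3000, 4000, repName = "MERVL-int", repFamily = "ERVL",
                repClass = "LTR"))
  # 10 fragments fully inside the first element
  m1 <- rep(gr0("chr1", 10, 60), 10)
  m2 <- rep(gr0("chr1", 500, 550), 10)
  fr <- PairedFragments(m1, m2, names = paste0("f", 1:10))
  tab <- countByRepName(fr, reps, inputReads = 2e6)
  expect_identical(repeatCounts(tab)["IAPLTR2_Mm", 1], 10L)
  # ambiguous: mate1 in L1, mate2 in adjacent MERVL element
  amb <- PairedFragments(gr0("chr1", 2100, 2150), gr0("chr1", 3100, 3150),
                         names = "a1")
  tab2 <- countByRepName(amb, reps, inputReads = 2e6)
  expect_true(all(repeatCounts(tab2) == 0))
  expect_identical(unname(tab2@ambiguousFragments), 1)
  expect_identical(bruteAssignOracle(firstMate(amb), secondMate(amb), reps),
                   NA_character_)
  # empty input: zero counts, lengths still reported
  tab3 <- countByRepName(PairedFragments(GenomicRanges::GRanges(),
                                         GenomicRanges::GRanges()),
                         reps, inputReads = 2e6)
  expect_true(all(repeatCounts(tab3) == 0))
  expect_identical(sort(names(summarizedLengthKb(tab3))),
                   sort(unique(reps$repName)))
})

test_that("counting matches the brute-force assignment oracle", {
  set.seed(33)
  reps <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = seq(1, 40000, by = 2000),
                     width = 1500),
    repFamily = "F", repClass = "LTR")
  reps$repName <- sample(c("A", "B"), length(reps), replace = TRUE)
  nF <- 200
  s1 <- sample(1:40000, nF)
  m1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s1, width = 40))
  m2 <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(s1 + sample(0:2200, nF, TRUE),
                                                width = 40))
  fr <- PairedFragments(m1, m2, names = paste0("f", 1:nF))
  kept <- filterRepeatFragments(fr, reps, GenomicRanges::GRanges())
  tab <- countByRepName(kept, reps, inputReads = 1e6)
  oracle <- bruteAssignOracle(firstMate(kept), secondMate(kept), reps)
  expected <- table(factor(oracle[!is.na(oracle)],
                           levels = rownames(repeatCounts(tab))))
  expect_identical(as.integer(expected), unname(repeatCounts(tab)[, 1]))
  expect_identical(unname(tab@ambiguousFragments), sum(is.na(oracle)) + 0)
})

test_that("repName FPKM follows the printed formula exactly", {
  mk <- function(count, inputReads, lengthKb) {
    new("RepeatCountTable",
        counts = matrix(as.integer(count), 1, 1,
                        dimnames = list("R", "s1")),
        lengthKb = c(R = lengthKb), inputReads = c(s1 = inputReads),
        nameToFamily = c(R = "F"), nameToClass = c(R = "LTR"),
        ambiguousFragments = c(s1 = 0))
  }
  expect_equal(fpkmValues(fpkmByRepName(mk(100, 2e6, 2)))[1, 1], 50)
  expect_equal(fpkmValues(fpkmByRepName(mk(1, 2e6, 1)))[1, 1], 1)
  expect_equal(fpkmValues(fpkmByRepName(mk(0, 2e6, 1)))[1, 1], 0)
  expect_equal(fpkmValues(fpkmByRepName(mk(250, 1e7, 0.5)))[1, 1], 100)
  expect_equal(fpkmValues(fpkmByRepName(mk(3, 6e6, 4)))[1, 1], 0.25)
  expect_error(fpkmByRepName(mk(1, 0, 1)), "> 0")
})

test_that("family FPKM aggregates counts and lengths, not member FPKMs", {
  tab <- new("RepeatCountTable",
             counts = matrix(c(10L, 30L), 2, 1,
                             dimnames = list(c("A", "B"), "s1")),
             lengthKb = c(A = 1, B = 3), inputReads = c(s1 = 2e6),
             nameToFamily = c(A = "FAM", B = "FAM"),
             nameToClass = c(A = "LTR", B = "LTR"),
             ambiguousFragments = c(s1 = 0))
  fam <- fpkmByRepFamily(tab)
  expect_equal(fpkmValues(fam)["FAM", 1], 10)
  # regression: the wrong formula (mean of member FPKMs) diverges whenever
  # member rates differ
  tabU <- tab
  tabU@counts <- matrix(c(10L, 60L), 2, 1,
                        dimnames = list(c("A", "B"), "s1"))
  perName <- fpkmValues(fpkmByRepName(tabU))
  famU <- fpkmValues(fpkmByRepFamily(tabU))["FAM", 1]
  expect_equal(famU, 17.5)
  expect_false(isTRUE(all.equal(mean(perName[, 1]), famU)))
  # single-member family equals the repName value
  tabB <- new("RepeatCountTable",
              counts = matrix(5L, 1, 1, dimnames = list("C", "s1")),
              lengthKb = c(C = 2), inputReads = c(s1 = 2e6),
              nameToFamily = c(C = "SOLO"), nameToClass = c(C = "LINE"),
              ambiguousFragments = c(s1 = 0))
  expect_equal(fpkmValues(fpkmByRepFamily(tabB))["SOLO", 1],
               fpkmValues(fpkmByRepName(tabB))["C", 1])
  # permuting element order leaves the output unchanged
  tabPerm <- new("RepeatCountTable",
                 counts = tab@counts[c(2, 1), , drop = FALSE],
                 lengthKb = tab@lengthKb[c(2, 1)],
                 inputReads = tab@inputReads,
                 nameToFamily = tab@nameToFamily[c(2, 1)],
                 nameToClass = tab@nameToClass[c(2, 1)],
                 ambiguousFragments = tab@ambiguousFragments)
  expect_equal(fpkmValues(fpkmByRepFamily(tabPerm))["FAM", 1], 10)
})

test_that("doubling input reads halves every FPKM exactly", {
  cfg <- SimConfig(seed = 6, meanDepthFragments = 2000)
  ann <- makeToyAnnotation(cfg)
  sim <- simulateFragments(cfg, ann)
  kept <- filterRepeatFragments(sim$fragments, ann$repeats, ann$genes)
  t1 <- countByRepName(kept, ann$repeats, inputReads = 1e6)
  t2 <- countByRepName(kept, ann$repeats, inputReads = 2e6)
  expect_equal(fpkmValues(fpkmByRepName(t1)), 2 * fpkmValues(fpkmByRepName(t2)))
})

test_that("DNA contamination covariate sums DNA-class FPKM and flags outliers", {
  mkF <- function(m, classes) {
    new("FpkmTable", level = "repName", fpkm = m, dnaFpkm = numeric(0),
        featureClass = classes)
  }
  m <- matrix(c(5, 15, 99), 3, 1,
              dimnames = list(c("d1", "d2", "ltr"), "A"))
  f <- dnaContamination(mkF(m, c(d1 = "DNA", d2 = "DNA", ltr = "LTR")))
  expect_equal(unname(dnaFpkm(f)["A"]), 20)
  # all zero: zero covariate, no flags
  m0 <- matrix(0, 2, 3, dimnames = list(c("d1", "d2"), c("A", "B", "C")))
  f0 <- dnaContamination(mkF(m0, c(d1 = "DNA", d2 = "DNA")))
  expect_true(all(dnaFpkm(f0) == 0))
  expect_false(any(attr(f0, "flagged")))
  # hand-computed median + 3 MAD: values 1,1.2,0.9,1.1,100 -> only the
  # last exceeds 1.1 + 3 * mad
  v <- c(1, 1.2, 0.9, 1.1, 100)
  mm <- matrix(v, 1, 5, dimnames = list("d1", paste0("s", 1:5)))
  fo <- dnaContamination(mkF(mm, c(d1 = "DNA")))
  expectFlag <- v > median(v) + 3 * mad(v)
  expect_identical(unname(attr(fo, "flagged")), expectFlag)
  expect_identical(sum(attr(fo, "flagged")), 1L)
  # no DNA-class features: warning, all-zero covariate
  expect_warning(
    fz <- dnaContamination(mkF(matrix(2, 1, 2,
                                      dimnames = list("x", c("A", "B"))),
                               c(x = "LTR"))),
    "no DNA-class")
  expect_true(all(dnaFpkm(fz) == 0))
})
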