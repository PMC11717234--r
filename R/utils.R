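#' @importFrom methods new validObject is slot show setValidity as
#' @importFrom stats median mad quantile rnbinom rpois rnorm runif rbinom
#'   optimize pnorm pchisq phyper p.adjust prcomp cor sd var rmultinom
#'   model.matrix setNames complete.cases dnbinom fisher.test chisq.test
#'   t.test wilcox.test lm coef lm.wfit qr.coef
#' @importFrom utils read.table write.table head tail
NULL

# Derive a deterministic sub-seed from a master seed and a fixed label, so
# that each generator draws from its own stream and adding a generator never
# perturbs another's fixtures. Result stays below 2^31 - 1.
streamSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0L
  for (ch in utf8ToInt(label)) h <- (h * 31L + ch) %% 1000003L
  as.integer((abs(seed) %% 2000000011 + as.numeric(h) * 1009) %% 2147483647)
}

# Run expr under a seeded, isolated RNG state (global .Random.seed restored).
withStream <- function(seed, label, expr) {
  withr::with_seed(streamSeed(seed, label), expr)
}

# Convert 0-based half-open intervals (BED convention) to an IRanges and back.
# GRanges/IRanges are 1-based closed; this is the single boundary conversion.
halfOpenToIRanges <- function(start0, end0) {
  if (any(end0 <= start0)) stop("interval end must exceed start")
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

irangesToHalfOpen <- function(x) {
  data.frame(start0 = BiocGenerics::start(x) - 1L, end0 = BiocGenerics::end(x))
}

#' @importFrom BiocGenerics start end width strand
NULL

# Write a data.frame as a deterministic TSV (fixed quoting/NA conventions so
# reruns are byte-identical).
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

readTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
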