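#' Load a repeat annotation, optionally excluding simple repeats
#'
#' Parses either the RepeatMasker \code{.out} dialect (1-based closed
#' coordinates, class/family combined as \code{class/family}) or an extended
#' BED (0-based half-open, columns 7-9 = repName/repFamily/repClass) into a
#' GRanges. With \code{excludeSimple = TRUE} (the default, matching the
#' analysis convention) rows of class Simple_repeat or Low_complexity are
#' dropped. The repName to (repFamily, repClass) mapping must be functional.
#'
#' @param path file path.
#' @param format "auto" (by extension: .out vs anything else), "rmout" or
#'   "bed".
#' @param excludeSimple drop Simple_repeat / Low_complexity rows.
#' @return GRanges with repName, repFamily, repClass, elementId.
#' @export
loadRepeatAnnotation <- function(path, format = c("auto", "rmout", "bed"),
                                 excludeSimple = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.out$", path)) "rmout" else "bed"
  if (format == "rmout") {
    lines <- readLines(path)
    body <- lines[-seq_len(min(3L, length(lines)))]
    body <- body[nzchar(trimws(body))]
    rows <- strsplit(trimws(body), "\\s+")
    df <- do.call(rbind, lapply(seq_along(rows), function(i) {
      f <- rows[[i]]
      if (length(f) < 11L)
        stop("malformed RepeatMasker row at line ", i + 3L)
      cf <- strsplit(f[11], "/", fixed = TRUE)[[1]]
      data.frame(chrom = f[5], start = as.integer(f[6]), end = as.integer(f[7]),
                 strand = ifelse(f[9] == "C", "-", "+"), repName = f[10],
                 repClass = cf[1],
                 repFamily = if (length(cf) > 1) cf[2] else cf[1],
                 line = i + 3L, stringsAsFactors = FALSE)
    }))
    bad <- which(is.na(df$start) | is.na(df$end) | df$end < df$start)
    if (length(bad))
      stop("malformed coordinates at line ", df$line[bad[1]])
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
  } else {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 9L) stop("extended BED needs 9 columns")
    colnames(df)[1:9] <- c("chrom", "start0", "end0", "name", "score",
                           "strand", "repName", "repFamily", "repClass")
    bad <- which(is.na(df$start0) | is.na(df$end0) | df$end0 <= df$start0)
    if (length(bad)) stop("malformed interval (end <= start) at line ", bad[1])
    gr <- GenomicRanges::GRanges(df$chrom,
                                 halfOpenToIRanges(df$start0, df$end0),
                                 strand = ifelse(df$strand %in% c("+", "-"),
                                                 df$strand, "*"))
  }
  gr$repName <- df$repName
  gr$repFamily <- df$repFamily
  gr$repClass <- df$repClass
  ## functional mapping check: one family/class per repName
  map <- unique(data.frame(n = gr$repName, f = gr$repFamily, c = gr$repClass))
  if (anyDuplicated(map$n))
    stop("inconsistent repFamily/repClass for repName(s): ",
         paste(unique(map$n[duplicated(map$n)]), collapse = ", "))
  if (excludeSimple)
    gr <- gr[!gr$repClass %in% c("Simple_repeat", "Low_complexity")]
  gr$elementId <- paste0("rep_e", seq_along(gr))
  gr
}

#' Write a repeat annotation as RepeatMasker .out dialect
#' @param repeats GRanges with repName/repFamily/repClass.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRepeatMaskerOut <- function(repeats, path) {
  hdr <- c("   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
           "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
           "")
  cf <- ifelse(repeats$repClass == repeats$repFamily, repeats$repClass,
               paste0(repeats$repClass, "/", repeats$repFamily))
  rows <- sprintf("%5d %5.1f %4.1f %4.1f  %s %8d %8d (%d) %s %s %s %6d %5d (%d) %5d",
                  1000L, 1.0, 0.0, 0.0,
                  as.character(GenomicRanges::seqnames(repeats)),
                  BiocGenerics::start(repeats), BiocGenerics::end(repeats), 0L,
                  ifelse(as.character(BiocGenerics::strand(repeats)) == "-",
                         "C", "+"),
                  repeats$repName, cf, 1L, GenomicRanges::width(repeats), 0L,
                  seq_along(repeats))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a repeat annotation as extended BED (0-based half-open)
#' @inheritParams writeRepeatMaskerOut
#' @export
writeRepeatBed <- function(repeats, path) {
  ho <- irangesToHalfOpen(IRanges::ranges(repeats))
  df <- data.frame(as.character(GenomicRanges::seqnames(repeats)),
                   ho$start0, ho$end0, repeats$repName, 0L,
                   as.character(BiocGenerics::strand(repeats)),
                   repeats$repName, repeats$repFamily, repeats$repClass)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write gene annotation as GTF
#' @param genes GRanges with gene_id (and optional geneType).
#' @param path output path.
#' @export
writeGeneGtf <- function(genes, path) {
  attr. <- sprintf('gene_id "%s"; gene_type "%s";', genes$gene_id,
                   if (!is.null(genes$geneType)) genes$geneType else "gene")
  rows <- paste(as.character(GenomicRanges::seqnames(genes)), "toy", "gene",
                BiocGenerics::start(genes), BiocGenerics::end(genes), ".",
                as.character(BiocGenerics::strand(genes)), ".", attr.,
                sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Load gene annotation from GTF
#' @param path GTF path.
#' @return GRanges with gene_id, geneType, lengthKb.
#' @export
loadGeneGtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene" | is.na(gr$type)]
  if (is.null(gr$geneType) && !is.null(gr$gene_type)) gr$geneType <- gr$gene_type
  gr$lengthKb <- GenomicRanges::width(gr) / 1000
  gr
}

#' Read paired-end fragments from a SAM file
#'
#' Converts the SAM to BAM (Rsamtools) and reads proper pairs with
#' GenomicAlignments; returns the mate intervals as
#' \linkS4class{PairedFragments}, ordered as in the file's pairing.
#'
#' @param samPath path to a headered SAM file.
#' @return a \linkS4class{PairedFragments}.
#' @export
readFragmentsSam <- function(samPath) {
  bam <- Rsamtools::asBam(samPath,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = TRUE)
  gap <- GenomicAlignments::readGAlignmentPairs(
    bam, use.names = TRUE,
    param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isPaired = TRUE)))
  m1 <- GenomicRanges::granges(GenomicAlignments::first(gap))
  m2 <- GenomicRanges::granges(GenomicAlignments::second(gap))
  BiocGenerics::strand(m1) <- "*"
  BiocGenerics::strand(m2) <- "*"
  PairedFragments(m1, m2, names = names(gap))
}

#' Extract single-end reads over a locus window from a SAM file
#'
#' Returns the read sequences (soft-clipped bases included, as stored in the
#' SEQ field), CIGAR strings and positions of unpaired reads overlapping the
#' given window — the input expected by \code{\link{callAlleleAtLocus}}.
#'
#' @param samPath path to a headered SAM file.
#' @param region GRanges of length 1, the locus window.
#' @return data.frame with qname, seq, cigar, pos.
#' @export
readLocusReadsSam <- function(samPath, region) {
  bam <- Rsamtools::asBam(samPath,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = TRUE)
  ga <- GenomicAlignments::readGAlignments(
    bam, use.names = TRUE,
    param = Rsamtools::ScanBamParam(
      what = c("seq", "pos"),
      flag = Rsamtools::scanBamFlag(isPaired = FALSE),
      which = region))
  data.frame(qname = names(ga),
             seq = as.character(S4Vectors::mcols(ga)$seq),
             cigar = GenomicAlignments::cigar(ga),
             pos = BiocGenerics::start(ga),
             stringsAsFactors = FALSE)
}

#' Write / read a counts matrix as TSV (features x samples)
#' @param counts integer matrix with dimnames.
#' @param path output path.
#' @export
writeCountsTsv <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  writeTsv(df, path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Serialize a SimConfig to YAML and back
#' @param config a \linkS4class{SimConfig}.
#' @param path YAML path.
#' @export
writeSimConfigYaml <- function(config, path) {
  x <- list(seed = config@seed, nChromosomes = config@nChromosomes,
            chromLengthBp = config@chromLengthBp,
            nRepeatElements = config@nRepeatElements,
            repnameCatalog = as.list(config@repnameCatalog),
            nGenes = config@nGenes,
            nSamplesPerGroup = config@nSamplesPerGroup,
            meanDepthFragments = config@meanDepthFragments,
            nbDispersion = config@nbDispersion,
            effectLog2FC = as.list(config@effectLog2FC),
            dnaContaminationFraction = config@dnaContaminationFraction,
            batchStrength = config@batchStrength,
            alleleMix = if (nrow(config@alleleMix)) asplit(config@alleleMix, 1) else list())
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeSimConfigYaml
#' @export
readSimConfigYaml <- function(path) {
  x <- yaml::read_yaml(path)
  am <- if (length(x$alleleMix)) {
    m <- do.call(rbind, lapply(x$alleleMix, unlist))
    colnames(m) <- c("wt", "missense", "deletion")
    m
  } else matrix(numeric(0), 0, 3,
                dimnames = list(NULL, c("wt", "missense", "deletion")))
  SimConfig(seed = x$seed, nChromosomes = x$nChromosomes,
            chromLengthBp = x$chromLengthBp,
            nRepeatElements = x$nRepeatElements,
            repnameCatalog = as.data.frame(x$repnameCatalog),
            nGenes = x$nGenes, nSamplesPerGroup = x$nSamplesPerGroup,
            meanDepthFragments = x$meanDepthFragments,
            nbDispersion = x$nbDispersion,
            effectLog2FC = unlist(x$effectLog2FC) %||% numeric(0),
            dnaContaminationFraction = x$dnaContaminationFraction,
            batchStrength = x$batchStrength, alleleMix = am)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
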