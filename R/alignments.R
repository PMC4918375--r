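#' Load mapped iCLIP fragments from a BAM or SAM file
#'
#' One [clip_fragments] row per primary alignment passing the mapping
#' quality filter. Aligned blocks come from the CIGAR (match/deletion
#' segments; `N` gaps split blocks, i.e. introns). The random barcode and
#' adapter group must be recoverable from the read name, encoded as
#' `origid#BC:<barcode>#GR:<A|B>` -- the convention written by
#' [write_fastq()] and [write_sam()], which survives any aligner.
#'
#' @param path a BAM file, or a SAM file (converted on the fly).
#' @param min_mapq minimal alignment quality kept (default 10; unavailable
#'   mapping qualities encoded as 255 pass).
#' @return A [clip_fragments] table with attributes `n_records`,
#'   `n_skipped` (unmapped/secondary/supplementary) and `n_low_mapq`.
#' @export
load_fragments <- function(path, min_mapq = 10L) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  total <- sum(Rsamtools::countBam(path)$records)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  gal <- GenomicAlignments::readGAlignments(path, param = param)
  n_primary <- length(gal)
  mapq <- S4Vectors::mcols(gal)$mapq
  keep <- is.na(mapq) | mapq >= min_mapq | mapq == 255L
  gal <- gal[keep]
  qn <- S4Vectors::mcols(gal)$qname
  m <- regmatches(qn, regexec("#BC:([ACGTN]+)#GR:([AB])", qn))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("read '", qn[which(bad)[1L]],
         "' carries no #BC:/#GR: barcode annotation")
  barcode <- vapply(m, `[`, character(1), 2L)
  group <- vapply(m, `[`, character(1), 3L)
  rl <- GenomicAlignments::grglist(gal)
  starts <- split(BiocGenerics::start(BiocGenerics::unlist(rl)) - 1L,
                  rep(seq_along(rl), S4Vectors::elementNROWS(rl)))
  ends <- split(BiocGenerics::end(BiocGenerics::unlist(rl)),
                rep(seq_along(rl), S4Vectors::elementNROWS(rl)))
  frags <- clip_fragments(
    chrom = as.character(GenomicRanges::seqnames(gal)),
    strand = as.character(BiocGenerics::strand(gal)),
    starts = unname(starts), ends = unname(ends),
    group = group, barcode = barcode,
    mapq = ifelse(is.na(mapq[keep]), 255L, mapq[keep]))
  attr(frags, "n_records") <- total
  attr(frags, "n_skipped") <- total - n_primary
  attr(frags, "n_low_mapq") <- n_primary - sum(keep)
  frags
}
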