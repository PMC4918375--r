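#' Build a splice junction catalog from exon annotation
#'
#' Every internal exon boundary of every multi-exon transcript yields two
#' junction entries: the 5' splice site class `exon_end_5ss` (boundary
#' between the last exonic and first intronic base, in transcript
#' orientation) and the 3' splice site class `exon_start_3ss` (last intronic
#' / first exonic base). The stored `coordinate` is the 0-based genomic
#' position of the first base on the 3' side of the boundary in transcript
#' orientation, so that [signed_distance()] of the last exonic base to its
#' 5'ss is -1. Duplicate junctions across transcripts are collapsed.
#'
#' @param exons data.frame with columns `chrom`, `strand`, `start`, `end`
#'   (0-based half-open genomic exon coordinates) and `transcript_id`.
#' @return data.frame of class `junction_catalog` with columns `chrom`,
#'   `strand`, `coordinate`, `class`.
#' @export
junction_catalog_from_exons <- function(exons) {
  dt <- data.table::as.data.table(exons[, c("chrom", "strand", "start", "end",
                                            "transcript_id")])
  bad <- dt$start >= dt$end
  if (any(bad)) {
    warning(sum(bad), " malformed exon records skipped")
    dt <- dt[!bad]
  }
  data.table::setorder(dt, transcript_id, start)
  jn <- dt[, {
    if (.N > 1L) {
      don <- end[-.N]       # genomic right edge of exon i (half-open)
      acc <- start[-1L]     # genomic left edge of exon i+1
      if (strand[1L] == "+") {
        list(coordinate = c(don, acc),
             class = rep(c("exon_end_5ss", "exon_start_3ss"), each = .N - 1L),
             chrom = chrom[1L], strand = strand[1L])
      } else {
        list(coordinate = c(acc - 1L, don - 1L),
             class = rep(c("exon_end_5ss", "exon_start_3ss"), each = .N - 1L),
             chrom = chrom[1L], strand = strand[1L])
      }
    }
  }, by = "transcript_id"]
  if (!nrow(jn)) {
    out <- data.frame(chrom = character(), strand = character(),
                      coordinate = integer(), class = character())
  } else {
    out <- unique(as.data.frame(jn[, c("chrom", "strand", "coordinate", "class")]))
    out <- out[order(out$chrom, out$strand, out$coordinate, out$class), ]
    rownames(out) <- NULL
  }
  class(out) <- c("junction_catalog", "data.frame")
  out
}

#' @rdname junction_catalog_from_exons
#' @param gtf path to a GTF/GFF file (Ensembl dialect) with exon features
#'   carrying `transcript_id` attributes.
#' @export
junction_catalog <- function(gtf) {
  gr <- rtracklayer::import(gtf)
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features found in ", gtf)
  exons <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    transcript_id = as.character(gr$transcript_id),
    stringsAsFactors = FALSE)
  junction_catalog_from_exons(exons)
}

#' Signed transcript-orientation distance from an anchor to a junction
#'
#' Negative values mean the anchor lies 5' (upstream) of the boundary in
#' transcript orientation; the last base on the 5' side of the boundary is
#' at -1 and the first base on the 3' side at 0. An anchor 24 nt upstream
#' of an exon-exon junction therefore returns -24.
#'
#' @param chrom,strand,pos anchor coordinates (0-based positions).
#' @param junction one row of a [junction_catalog_from_exons()] catalog (or
#'   a data.frame recycled against the anchors).
#' @return Integer vector of signed distances.
#' @export
signed_distance <- function(chrom, strand, pos, junction) {
  jc <- rep_len(junction$chrom, length(pos))
  js <- rep_len(junction$strand, length(pos))
  jx <- rep_len(junction$coordinate, length(pos))
  if (any(chrom != jc)) stop("anchor and junction on different chromosomes")
  if (any(strand != js)) stop("anchor and junction on different strands")
  as.integer(ifelse(strand == "+", pos - jx, jx - pos))
}

# all (anchor, junction) pairs with signed offset inside `window`;
# anchors within the window of several junctions count toward each.
# Returns data.table(idx = anchor index, offset).
.junction_offsets <- function(chrom, strand, pos, catalog, junction_class,
                              window) {
  cls <- switch(junction_class,
    "5ss" = "exon_end_5ss", "3ss" = "exon_start_3ss", junction_class)
  jdt <- data.table::as.data.table(catalog)[class == cls]
  if (!nrow(jdt)) stop("no junctions of class '", cls, "' in catalog")
  adt <- data.table::data.table(chrom = chrom, strand = strand, pos = pos,
                                idx = seq_along(pos))
  # offset = pos - coord on '+', coord - pos on '-': precompute scan bounds
  jdt[, lo := ifelse(strand == "+", coordinate + window[1L],
                     coordinate - window[2L])]
  jdt[, hi := ifelse(strand == "+", coordinate + window[2L],
                     coordinate - window[1L])]
  hits <- adt[jdt, on = .(chrom, strand, pos >= lo, pos <= hi),
              allow.cartesian = TRUE, nomatch = NULL,
              .(idx = x.idx, apos = x.pos, strand = x.strand,
                jcoord = i.coordinate)]
  hits[, offset := ifelse(strand == "+", apos - jcoord, jcoord - apos)]
  hits[, .(idx, offset)]
}

#' Write exon models as a GTF file
#'
#' @param exons data.frame as in [junction_catalog_from_exons()], optionally
#'   with a `gene_id` column.
#' @param path output path.
#' @param source value for the GTF source column.
#' @export
write_gtf <- function(exons, path, source = "iclipfrag") {
  gid <- if (!is.null(exons$gene_id)) exons$gene_id else exons$transcript_id
  lines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    exons$chrom, source, exons$start + 1L, exons$end, exons$strand,
    gid, exons$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Export junctions or anchors as BED6
#'
#' @param catalog a junction catalog (uses `coordinate` as a 1-bp interval).
#' @param path output path.
#' @export
write_junctions_bed <- function(catalog, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   catalog$chrom, catalog$coordinate, catalog$coordinate + 1L,
                   catalog$class, catalog$strand)
  writeLines(lines, path)
  invisible(path)
}
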