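#' Construct a table of mapped iCLIP fragments
#'
#' A `clip_fragments` object is a data.frame with one row per deduplicatable
#' mapped fragment. All genomic coordinates are 0-based half-open. Spliced
#' fragments carry their aligned blocks (gaps are introns) in the `blocks`
#' list column; unspliced fragments keep `blocks` as `NULL` and are handled
#' by a fast vectorized path throughout the package.
#'
#' @param chrom character vector of reference names.
#' @param strand character vector, `"+"` or `"-"`.
#' @param starts,ends either integer vectors (one aligned block per fragment)
#'   or lists of integer vectors giving the block starts/ends of each
#'   fragment, 0-based half-open, ascending and non-overlapping.
#' @param group `"A"` (completely sequenced, true length known) or `"B"`
#'   (read ran out before the 3' adapter; length is a lower bound).
#' @param barcode random barcode (UMI) carried by the read, used for
#'   deduplication.
#' @param mapq alignment quality score.
#' @return A data.frame of class `clip_fragments` with columns `chrom`,
#'   `strand`, `gstart`, `gend`, `length`, `nblocks`, `blocks`, `group`,
#'   `barcode`, `mapq`.
#' @export
clip_fragments <- function(chrom, strand, starts, ends,
                           group = "A", barcode = NA_character_,
                           mapq = NA_integer_) {
  if (is.list(starts) != is.list(ends))
    stop("'starts' and 'ends' must both be vectors or both be lists")
  if (is.list(starts)) {
    n <- length(starts)
    if (length(ends) != n) stop("block start/end lists differ in length")
    nb <- lengths(starts)
    if (!all(nb == lengths(ends))) stop("block start/end counts differ")
    gstart <- vapply(starts, function(x) as.integer(x[1L]), integer(1))
    gend <- vapply(ends, function(x) as.integer(x[length(x)]), integer(1))
    len <- mapply(function(s, e) sum(e - s), starts, ends)
    blocks <- vector("list", n)
    multi <- which(nb > 1L)
    for (i in multi) {
      b <- cbind(start = as.integer(starts[[i]]), end = as.integer(ends[[i]]))
      if (is.unsorted(b[, 1L], strictly = TRUE) ||
          any(b[, 1L] >= b[, 2L]) ||
          any(b[-1L, 1L] < b[-nrow(b), 2L]))
        stop("fragment ", i, ": blocks must be ascending, non-empty, non-overlapping")
      blocks[[i]] <- b
    }
  } else {
    n <- length(starts)
    gstart <- as.integer(starts)
    gend <- as.integer(ends)
    nb <- rep.int(1L, n)
    len <- gend - gstart
    blocks <- vector("list", n)
  }
  if (any(len <= 0L)) stop("fragment lengths must be > 0")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out <- data.frame(
    chrom = as.character(rep_len(chrom, n)),
    strand = as.character(rep_len(strand, n)),
    gstart = gstart, gend = gend,
    length = as.integer(len), nblocks = as.integer(nb),
    group = as.character(rep_len(group, n)),
    barcode = as.character(rep_len(barcode, n)),
    mapq = as.integer(rep_len(mapq, n)),
    stringsAsFactors = FALSE
  )
  out$blocks <- blocks
  class(out) <- c("clip_fragments", "data.frame")
  out
}

#' @export
print.clip_fragments <- function(x, ...) {
  cat(sprintf("clip_fragments: %d fragments (%d group A, %d group B, %d spliced)\n",
              nrow(x), sum(x$group == "A"), sum(x$group == "B"),
              sum(x$nblocks > 1L)))
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x)[setdiff(names(x), "blocks")], 6L)
    print(show)
    if (nrow(x) > 6L) cat("...\n")
  }
  invisible(x)
}

# genomic position of the aligned base at 0-based index i counted from the
# genomic left end of the fragment (vectorized; slow path only for spliced)
.aligned_base_left <- function(frags, i) {
  pos <- frags$gstart + i
  multi <- which(frags$nblocks > 1L)
  for (k in multi) {
    b <- frags$blocks[[k]]
    w <- b[, 2L] - b[, 1L]
    cw <- cumsum(w)
    j <- findInterval(i[k], cw) + 1L          # block holding index i
    before <- if (j > 1L) cw[j - 1L] else 0L
    pos[k] <- b[j, 1L] + (i[k] - before)
  }
  as.integer(pos)
}

#' Anchor coordinates of fragments
#'
#' Extracts, per fragment, the 0-based genomic coordinate of the chosen
#' anchor in transcript orientation: `start` is the 5'-most aligned base,
#' `end` the 3'-most, `centre` the aligned base at transcript offset
#' `floor((length - 1) / 2)` from the start (projected through splice
#' blocks, so spliced fragments get a centre on an exon; for even lengths
#' the 5' member of the central pair is taken), and `crosslink` the base
#' 1 nt 5' of the start -- the putative crosslink site under reverse
#' transcriptase truncation.
#'
#' @param frags a [clip_fragments] table.
#' @param kind one of `"start"`, `"centre"`, `"end"`, `"crosslink"`.
#' @return Integer vector of 0-based genomic positions. A `crosslink`
#'   anchor of a fragment starting at position 0 of its chromosome is
#'   returned as -1; downstream map builders drop such positions.
#' @export
anchor_positions <- function(frags,
                             kind = c("start", "centre", "end", "crosslink")) {
  kind <- match.arg(kind)
  plus <- frags$strand == "+"
  switch(kind,
    start = as.integer(ifelse(plus, frags$gstart, frags$gend - 1L)),
    end = as.integer(ifelse(plus, frags$gend - 1L, frags$gstart)),
    crosslink = as.integer(ifelse(plus, frags$gstart - 1L, frags$gend)),
    centre = {
      o <- (frags$length - 1L) %/% 2L
      i <- ifelse(plus, o, frags$length - 1L - o)
      .aligned_base_left(frags, as.integer(i))
    }
  )
}

#' Remove PCR duplicates using random barcodes
#'
#' Fragments sharing the same chromosome, strand, 5' start position (in
#' transcript orientation -- the coordinate that identifies the cDNA under
#' truncation) and random barcode are collapsed to a single representative:
#' the longest one, ties broken by input order. Output order follows input
#' order of the kept representatives, so the operation is deterministic and
#' idempotent.
#'
#' @param frags a [clip_fragments] table.
#' @return A [clip_fragments] table with attributes `n_in`, `n_removed`.
#' @export
deduplicate <- function(frags) {
  if (!nrow(frags)) return(frags)
  p5 <- anchor_positions(frags, "start")
  dt <- data.table::data.table(
    chrom = frags$chrom, strand = frags$strand, p5 = p5,
    barcode = frags$barcode, len = frags$length, idx = seq_len(nrow(frags))
  )
  data.table::setorder(dt, chrom, strand, p5, barcode, -len, idx)
  keep <- dt[!duplicated(dt, by = c("chrom", "strand", "p5", "barcode")), idx]
  keep <- sort(keep)
  out <- frags[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_in") <- nrow(frags)
  attr(out, "n_removed") <- nrow(frags) - length(keep)
  out
}
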