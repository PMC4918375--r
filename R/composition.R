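#' Base composition around fragment starts or ends
#'
#' Strand-aware nucleotide frequency matrix in a window of `K` nt on each
#' side of the chosen anchor, in transcript orientation (sequences on the
#' minus strand are reverse-complemented). Position labels are relative to
#' the anchored fragment base at 0, so for the start anchor the putative
#' crosslink nucleotide sits at -1. When a junction catalog is supplied the
#' analysis is restricted to fragments whose crosslink position lies in the
#' predominant binding region 1-100 nt upstream of a junction of the chosen
#' class (configurable via `region`). Windows running off a contig end are
#' truncated; the per-position fragment count `n` records the bookkeeping.
#'
#' End composition reflects the RNase cleavage site and is only meaningful
#' for fragments with a defined 3' end, so `anchor = "end"` restricts to
#' group A fragments.
#'
#' @param frags a [clip_fragments] table.
#' @param genome a named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param catalog optional junction catalog for the region filter.
#' @param anchor `"start"` or `"end"`.
#' @param K window half-width in nt (default 10).
#' @param region integer `c(lo, hi)`: keep fragments whose crosslink is
#'   `lo..hi` nt upstream of a junction (default `c(1, 100)`).
#' @param junction junction class for the region filter (default `"5ss"`).
#' @param length_class `"all"`, `"A"` or `"B"`.
#' @return A list of class `clip_basecomp`: `freqs` and `counts` (4 x 2K+1
#'   matrices over A/C/G/T, columns labelled -K..K), `n` per position,
#'   `n_fragments`, plus the parameters.
#' @export
base_composition <- function(frags, genome, catalog = NULL,
                             anchor = c("start", "end"), K = 10L,
                             region = c(1L, 100L),
                             junction = c("5ss", "3ss"),
                             length_class = c("all", "A", "B")) {
  anchor <- match.arg(anchor)
  junction <- match.arg(junction)
  length_class <- match.arg(length_class)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (length_class != "all")
    frags <- frags[frags$group == length_class, , drop = FALSE]
  if (anchor == "end") frags <- frags[frags$group == "A", , drop = FALSE]
  if (!is.null(catalog) && nrow(frags)) {
    xl <- anchor_positions(frags, "crosslink")
    keepx <- xl >= 0L
    hits <- .junction_offsets(frags$chrom[keepx], frags$strand[keepx], xl[keepx],
                              catalog, junction,
                              c(-region[2L], -region[1L]))
    frags <- frags[which(keepx)[unique(hits$idx)], , drop = FALSE]
  }
  if (!nrow(frags)) stop("no fragments left for base composition")
  pos <- anchor_positions(frags, anchor)
  clen <- Biostrings::width(genome)[match(frags$chrom, names(genome))]
  if (anyNA(clen)) stop("fragment chromosome missing from genome")
  lo <- pos - K
  hi <- pos + K
  cl_lo <- pmax(lo, 0L)
  cl_hi <- pmin(hi, clen - 1L)
  seqs <- character(nrow(frags))
  for (ch in unique(frags$chrom)) {
    sel <- frags$chrom == ch
    v <- Biostrings::extractAt(genome[[ch]],
                               IRanges::IRanges(cl_lo[sel] + 1L, cl_hi[sel] + 1L))
    seqs[sel] <- as.character(v)
  }
  # pad truncated windows with N so positions stay aligned
  padl <- cl_lo - lo
  padr <- hi - cl_hi
  seqs <- paste0(strrep("N", padl), seqs, strrep("N", padr))
  dss <- Biostrings::DNAStringSet(seqs)
  minus <- frags$strand == "-"
  if (any(minus)) dss[minus] <- Biostrings::reverseComplement(dss[minus])
  cm <- Biostrings::consensusMatrix(dss)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, 4L, 2L * K + 1L, dimnames = list(bases, (-K):K))
  present <- intersect(bases, rownames(cm))
  counts[present, ] <- cm[present, , drop = FALSE]
  n <- colSums(counts)
  freqs <- sweep(counts, 2L, ifelse(n > 0, n, 1L), "/")
  structure(list(freqs = freqs, counts = counts, n = n,
                 n_fragments = nrow(frags), anchor = anchor, K = K,
                 length_class = length_class),
            class = "clip_basecomp")
}

#' @export
print.clip_basecomp <- function(x, ...) {
  cat(sprintf("clip_basecomp: %s anchor, %d fragments, positions %d..%d\n",
              x$anchor, x$n_fragments, -x$K, x$K))
  print(round(x$freqs, 3))
  invisible(x)
}

#' Write a base composition matrix as a logo-ready TSV
#'
#' @param x a `clip_basecomp`.
#' @param path output path.
#' @export
write_basecomp_tsv <- function(x, path) {
  df <- data.frame(position = as.integer(colnames(x$freqs)),
                   t(x$freqs), n = x$n, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
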