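#' Configuration for the annotation-free read overlap analysis
#'
#' The genome is tiled per chromosome and strand into non-overlapping
#' segments; segments holding at least `min_reads` fragments (by their start
#' anchor) are analysed. Within each segment the anchor positions of the
#' reference fragments define the 0-positions, and the offsets of every
#' query fragment's anchor to every 0-position within `-offset_window..
#' +offset_window` are recorded, stratified by query fragment length.
#'
#' @param segment_size segment width in nt (default 300).
#' @param min_reads minimal fragments per segment (default 50; use 20 for
#'   low-coverage libraries).
#' @param offset_window scan half-width in nt around each 0-position.
#' @param reference `"B"` to use the length-censored group B fragments as
#'   reference, or an integer range `c(lo, hi)` to use completely sequenced
#'   group A fragments of those lengths (e.g. `c(33, 39)`).
#' @param anchor which fragment position defines both the 0-positions and
#'   the query offsets: `"start"`, `"centre"` or `"end"`.
#' @param flank extra flank added to the length-specific maximal offset in
#'   the start site overlap ratio (default 5 nt).
#' @param read_length effective (post-barcode) sequencing read length in nt;
#'   group B fragments are censored at this length, and it determines the
#'   length-specific maximal centre offset in the ratio.
#' @param query `"auto"` uses group A fragments as queries when A/B labels
#'   exist and all fragments otherwise (HITS-CLIP mode); `"A"` or `"all"`
#'   force the choice.
#' @param distinct_reference_positions if `FALSE` (default) every reference
#'   fragment contributes its anchor position as a 0-position, so positions
#'   shared by several reference fragments carry their multiplicity -- the
#'   co-occurrence counting of the original method. `TRUE` collapses them
#'   to distinct positions.
#' @param maxoff_rounding `"floor"` (default) or `"ceil"` for the
#'   length-specific maximal offset `(read_length - L) / 2`.
#' @param indeterminate_band mean-ratio band reported as `indeterminate`.
#' @return A list of class `overlap_config`.
#' @export
overlap_config <- function(segment_size = 300L, min_reads = 50L,
                           offset_window = 50L, reference = "B",
                           anchor = c("start", "centre", "end"),
                           flank = 5L, read_length = NULL,
                           query = c("auto", "A", "all"),
                           distinct_reference_positions = FALSE,
                           maxoff_rounding = c("floor", "ceil"),
                           indeterminate_band = c(0.95, 1.05)) {
  anchor <- match.arg(anchor)
  query <- match.arg(query)
  maxoff_rounding <- match.arg(maxoff_rounding)
  stopifnot(segment_size > 0L, min_reads >= 1L, offset_window >= 1L)
  if (!(identical(reference, "B") ||
        (is.numeric(reference) && length(reference) == 2L &&
         reference[1L] <= reference[2L])))
    stop("reference must be \"B\" or an integer length range c(lo, hi)")
  structure(list(segment_size = as.integer(segment_size),
                 min_reads = as.integer(min_reads),
                 offset_window = as.integer(offset_window),
                 reference = reference, anchor = anchor,
                 flank = as.integer(flank),
                 read_length = if (is.null(read_length)) NULL
                               else as.integer(read_length),
                 query = query,
                 distinct_reference_positions = distinct_reference_positions,
                 maxoff_rounding = maxoff_rounding,
                 indeterminate_band = indeterminate_band),
            class = "overlap_config")
}

# fragments annotated with segment id + eligibility, as a data.table
.segment_table <- function(frags, config) {
  dt <- data.table::data.table(
    idx = seq_len(nrow(frags)),
    chrom = frags$chrom, strand = frags$strand,
    spos = anchor_positions(frags, "start"),
    length = frags$length, group = frags$group)
  dt[, seg := spos %/% config$segment_size]
  dt[, seg_n := .N, by = .(chrom, strand, seg)]
  dt[, eligible := seg_n >= config$min_reads]
  dt
}

#' Assign fragments to genomic segments and keep covered segments
#'
#' @param frags a deduplicated [clip_fragments] table.
#' @param config an [overlap_config()].
#' @return The fragments lying in eligible segments, with a `segment`
#'   column; attributes `n_segments` (eligible) and `n_segments_total`.
#' @export
segment_fragments <- function(frags, config = overlap_config()) {
  dt <- .segment_table(frags, config)
  keep <- dt$eligible
  out <- frags[dt$idx[keep], , drop = FALSE]
  out$segment <- if (any(keep))
    paste0(dt$chrom[keep], ":", dt$strand[keep], ":", dt$seg[keep])
  else character(0)
  rownames(out) <- NULL
  segs <- unique(dt[, .(chrom, strand, seg, eligible)])
  attr(out, "n_segments") <- sum(segs$eligible)
  attr(out, "n_segments_total") <- nrow(segs)
  if (!any(keep)) warning("no segment reaches min_reads = ", config$min_reads)
  out
}

#' Reference 0-positions of one set of segment fragments
#'
#' Resolves the reference selector of an [overlap_config()] against a
#' fragment table: group B fragments, or group A fragments within a length
#' range (all fragments within the range when no A/B split exists). Returns
#' the anchor positions, made distinct per segment when
#' `distinct_reference_positions` is set.
#'
#' @param frags a [clip_fragments] table (typically one segment's worth).
#' @param config an [overlap_config()].
#' @return Integer vector of 0-based 0-positions.
#' @export
reference_positions <- function(frags, config = overlap_config()) {
  sel <- .reference_mask(frags, config)
  pos <- anchor_positions(frags[sel, , drop = FALSE], config$anchor)
  if (config$distinct_reference_positions) pos <- unique(pos)
  pos
}

.reference_mask <- function(frags, config) {
  if (identical(config$reference, "B")) {
    frags$group == "B"
  } else {
    rng <- config$reference
    has_groups <- any(frags$group == "A") && any(frags$group == "B")
    inrange <- frags$length >= rng[1L] & frags$length <= rng[2L]
    if (has_groups) inrange & frags$group == "A" else inrange
  }
}

.query_mask <- function(frags, config) {
  has_groups <- any(frags$group == "A") && any(frags$group == "B")
  if (config$query == "A" || (config$query == "auto" && has_groups))
    frags$group == "A"
  else rep(TRUE, nrow(frags))
}

#' Annotation-free read overlap heatmap
#'
#' For every eligible segment, every reference 0-position and every query
#' fragment in the segment, records the offset of the query anchor to the
#' 0-position in transcript orientation (downstream = 3' = positive) into
#' the row of the query's fragment length, for offsets within the scan
#' window. Counts accumulate over all segments.
#'
#' @inheritParams segment_fragments
#' @return A list of class `clip_overlap`: `counts` (rows = query length,
#'   cols = offset -W..W), `n_segments` (eligible), `n_segments_used` (with
#'   at least one reference position), `n_reference` (total 0-positions),
#'   `n_query`, and the `config`.
#' @export
overlap_heatmap <- function(frags, config = overlap_config()) {
  W <- config$offset_window
  offs <- (-W):W
  dt <- .segment_table(frags, config)
  dt[, mpos := anchor_positions(frags, config$anchor)]
  el <- dt[eligible == TRUE]
  rmask <- .reference_mask(frags, config)
  qmask <- .query_mask(frags, config)
  refs <- el[rmask[idx], .(chrom, strand, seg, rpos = mpos)]
  if (config$distinct_reference_positions)
    refs <- unique(refs)
  qry <- el[qmask[idx], .(chrom, strand, seg, qpos = mpos, length)]
  lens <- sort(unique(qry$length))
  counts <- matrix(0L, nrow = length(lens), ncol = length(offs),
                   dimnames = list(lens, offs))
  n_used <- 0L
  if (nrow(refs) && nrow(qry)) {
    pairs <- qry[refs, on = .(chrom, strand, seg),
                 allow.cartesian = TRUE, nomatch = NULL]
    pairs[, offset := ifelse(strand == "+", qpos - rpos, rpos - qpos)]
    pairs <- pairs[abs(offset) <= W]
    tab <- pairs[, .N, by = .(length, offset)]
    if (nrow(tab))
      counts[cbind(match(tab$length, lens), tab$offset + W + 1L)] <- tab$N
    n_used <- nrow(unique(refs[, .(chrom, strand, seg)]))
  }
  segs <- unique(el[, .(chrom, strand, seg)])
  structure(list(counts = counts, offsets = offs, lengths = as.integer(lens),
                 n_segments = nrow(segs), n_segments_used = n_used,
                 n_reference = nrow(refs), n_query = nrow(qry),
                 config = config),
            class = "clip_overlap")
}

#' @export
print.clip_overlap <- function(x, ...) {
  cat(sprintf(paste0(
    "clip_overlap: %s-anchored, %d eligible segments (%d with references),\n",
    "  %d reference 0-positions, %d query fragments, %d length rows, ",
    "offsets %d..%d\n"),
    x$config$anchor, x$n_segments, x$n_segments_used, x$n_reference,
    x$n_query, length(x$lengths), -x$config$offset_window,
    x$config$offset_window))
  invisible(x)
}

#' Start site overlap ratio from a centre-anchored overlap heatmap
#'
#' For each query fragment length `L`, the maximal offset between the centre
#' of a query fragment and the centre of a (read-length censored) reference
#' fragment sharing its start is `(read_length - L) / 2` (rounded down by
#' default). The mean count per offset bin is taken over the upstream range
#' `[-(maxoff + flank), -1]` and the downstream range `[+1, +(maxoff +
#' flank)]` (offset 0, exact coincidence, counts toward neither side), both
#' clipped to the scan window, and their quotient is the start site overlap
#' ratio of that length. The report carries the per-length ratios and their
#' mean and median; a mean well above 1 indicates coinciding fragment start
#' sites (use start positions for binding-site assignment), a mean below 1
#' favours the fragment centres.
#'
#' @param hm a `clip_overlap` computed with `anchor = "centre"`, or a bare
#'   count matrix with length rownames and offset colnames.
#' @param config an [overlap_config()] with `read_length` set (taken from
#'   `hm` if missing).
#' @return A list of class `clip_ratio`: `per_length` data.frame (`length`,
#'   `upstream_mean`, `downstream_mean`, `ratio`), `mean_ratio`,
#'   `median_ratio`, `n_lengths`, `verdict`.
#' @export
ratio_from_heatmap <- function(hm, config = NULL) {
  if (inherits(hm, "clip_overlap")) {
    if (is.null(config)) config <- hm$config
    counts <- hm$counts
  } else counts <- hm
  if (is.null(config$read_length))
    stop("read_length must be set in the overlap_config for the ratio")
  W <- (ncol(counts) - 1L) %/% 2L
  offs <- as.integer(colnames(counts))
  lens <- as.integer(rownames(counts))
  rnd <- if (identical(config$maxoff_rounding, "ceil")) ceiling else floor
  per <- lapply(seq_along(lens), function(i) {
    L <- lens[i]
    maxoff <- rnd((config$read_length - L) / 2)
    hi <- min(maxoff + config$flank, W)
    if (maxoff < 0L || hi < 1L)
      return(data.frame(length = L, upstream_mean = NA_real_,
                        downstream_mean = NA_real_, ratio = NA_real_))
    up <- mean(counts[i, offs >= -hi & offs <= -1L])
    dn <- mean(counts[i, offs >= 1L & offs <= hi])
    data.frame(length = L, upstream_mean = up, downstream_mean = dn,
               ratio = if (dn > 0) up / dn else NA_real_)
  })
  per <- do.call(rbind, per)
  ok <- !is.na(per$ratio) & (per$upstream_mean + per$downstream_mean) > 0
  if (!any(ok)) stop("start site overlap ratio undefined for every length")
  mean_ratio <- mean(per$ratio[ok])
  median_ratio <- stats::median(per$ratio[ok])
  band <- config$indeterminate_band
  verdict <- if (mean_ratio > band[2L]) "start_based"
             else if (mean_ratio < band[1L]) "centre_based"
             else "indeterminate"
  structure(list(per_length = per, mean_ratio = mean_ratio,
                 median_ratio = median_ratio, n_lengths = sum(ok),
                 verdict = verdict, config = config),
            class = "clip_ratio")
}

#' @rdname ratio_from_heatmap
#' @param frags a deduplicated [clip_fragments] table.
#' @export
start_site_overlap_ratio <- function(frags, config = overlap_config()) {
  config$anchor <- "centre"
  hm <- overlap_heatmap(frags, config)
  ratio_from_heatmap(hm, config)
}

#' @export
print.clip_ratio <- function(x, ...) {
  cat(sprintf(
    "start site overlap ratio: mean %.3f, median %.3f over %d fragment lengths\n",
    x$mean_ratio, x$median_ratio, x$n_lengths))
  cat(sprintf("verdict: %s\n", x$verdict))
  invisible(x)
}

#' Write an overlap heatmap or ratio report as TSV
#'
#' @param x a `clip_overlap` or `clip_ratio`.
#' @param path output path.
#' @export
write_overlap_tsv <- function(x, path) {
  if (inherits(x, "clip_overlap")) {
    df <- data.frame(length = rownames(x$counts), x$counts, check.names = FALSE)
    data.table::fwrite(df, path, sep = "\t")
  } else if (inherits(x, "clip_ratio")) {
    data.table::fwrite(x$per_length, path, sep = "\t")
  } else stop("unsupported object")
  invisible(path)
}
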