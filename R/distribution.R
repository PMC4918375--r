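#' Junction-anchored read distribution curve
#'
#' Histogram of signed distances of a chosen fragment anchor (start, centre,
#' end, or the crosslink nucleotide preceding the start) to all junctions of
#' a class, restricted to a window around the boundary, for the whole
#' library or one of the adapter groups. Anchors falling in the window of
#' more than one junction contribute to each, as in standard metagene
#' practice.
#'
#' @param frags a [clip_fragments] table (deduplicated).
#' @param catalog a junction catalog.
#' @param anchor anchor kind, see [anchor_positions()].
#' @param junction `"5ss"` (exon end) or `"3ss"` (exon start).
#' @param window integer `c(lo, hi)` of signed offsets, default `-150..50`.
#' @param population `"all"`, `"A"` or `"B"`.
#' @return data.frame of class `clip_curve` with columns `offset`, `count`,
#'   `fraction`; attributes carry the parameters and fragment counts.
#' @export
distribution_curve <- function(frags, catalog,
                               anchor = c("crosslink", "start", "centre", "end"),
                               junction = c("5ss", "3ss"),
                               window = c(-150L, 50L),
                               population = c("all", "A", "B")) {
  anchor <- match.arg(anchor)
  junction <- match.arg(junction)
  population <- match.arg(population)
  stopifnot(window[1L] < window[2L])
  if (population != "all") frags <- frags[frags$group == population, , drop = FALSE]
  offs <- window[1L]:window[2L]
  if (!nrow(frags)) {
    warning("empty population '", population, "'; returning zero curve")
    counts <- integer(length(offs))
  } else {
    pos <- anchor_positions(frags, anchor)
    keep <- pos >= 0L
    hits <- .junction_offsets(frags$chrom[keep], frags$strand[keep], pos[keep],
                              catalog, junction, window)
    counts <- tabulate(hits$offset - window[1L] + 1L, nbins = length(offs))
  }
  tot <- sum(counts)
  out <- data.frame(offset = offs, count = counts,
                    fraction = if (tot > 0) counts / tot else 0)
  attr(out, "anchor") <- anchor
  attr(out, "junction") <- junction
  attr(out, "window") <- window
  attr(out, "population") <- population
  attr(out, "n_fragments") <- nrow(frags)
  class(out) <- c("clip_curve", "data.frame")
  out
}

#' Length-stratified junction-anchored heatmap
#'
#' One row per fragment length: the offset histogram of the chosen anchor
#' relative to junctions of a class, normalized by the number of fragments
#' of that length inside the analysed window. Exact length stratification is
#' only meaningful for completely sequenced group A fragments (the default
#' population); group B fragments are stratified by their observed
#' lower-bound length and the result is flagged as length-censored.
#'
#' @inheritParams distribution_curve
#' @param lengths optional integer vector of row lengths; defaults to all
#'   lengths observed in the population (rows with zero fragments in the
#'   window are kept as all-zero rows with `row_totals` 0).
#' @return A list of class `clip_distmatrix`: `counts` and `normalized`
#'   matrices (rows = length, cols = offset), `row_totals`, `offsets`,
#'   `lengths`, `censored`, plus the parameters.
#' @export
length_heatmap <- function(frags, catalog,
                           anchor = c("start", "centre", "end", "crosslink"),
                           junction = c("5ss", "3ss"),
                           window = c(-150L, 50L),
                           population = c("A", "B", "all"),
                           lengths = NULL) {
  anchor <- match.arg(anchor)
  junction <- match.arg(junction)
  population <- match.arg(population)
  stopifnot(window[1L] < window[2L])
  if (population != "all") frags <- frags[frags$group == population, , drop = FALSE]
  if (is.null(lengths))
    lengths <- if (nrow(frags)) sort(unique(frags$length)) else integer()
  offs <- window[1L]:window[2L]
  counts <- matrix(0L, nrow = length(lengths), ncol = length(offs),
                   dimnames = list(lengths, offs))
  if (nrow(frags)) {
    pos <- anchor_positions(frags, anchor)
    keep <- pos >= 0L
    hits <- .junction_offsets(frags$chrom[keep], frags$strand[keep], pos[keep],
                              catalog, junction, window)
    hits[, len := frags$length[which(keep)][idx]]
    tab <- hits[len %in% lengths, .N, by = .(len, offset)]
    if (nrow(tab)) {
      ri <- match(tab$len, lengths)
      ci <- tab$offset - window[1L] + 1L
      counts[cbind(ri, ci)] <- tab$N
    }
  }
  row_totals <- rowSums(counts)
  normalized <- counts / ifelse(row_totals > 0, row_totals, 1L)
  structure(list(counts = counts, normalized = normalized,
                 row_totals = row_totals, offsets = offs,
                 lengths = as.integer(lengths),
                 anchor = anchor, junction = junction, window = window,
                 population = population,
                 censored = population %in% c("B", "all")),
            class = "clip_distmatrix")
}

#' @export
print.clip_distmatrix <- function(x, ...) {
  cat(sprintf(
    "clip_distmatrix: %s anchor vs %s, window %d..%d, %d length rows (%s)\n",
    x$anchor, x$junction, x$window[1L], x$window[2L], length(x$lengths),
    if (x$censored) "length-censored population included" else "group A"))
  invisible(x)
}

#' Aggregate offset profile of a length-stratified heatmap
#'
#' Column sums of the raw count matrix: equals the [distribution_curve()]
#' computed over the same fragments.
#'
#' @param hm a `clip_distmatrix`.
#' @return data.frame with `offset`, `count`.
#' @export
column_profile <- function(hm) {
  data.frame(offset = hm$offsets, count = as.integer(colSums(hm$counts)))
}

#' Full width at half maximum of a positional distribution
#'
#' Computed on the raw (unsmoothed) histogram. The half-maximum level is
#' half the global maximum; the two crossing points are located by linear
#' interpolation between adjacent integer offsets on each flank, taking the
#' outermost crossings if the level is crossed more than twice (with a
#' warning). The curve is treated as falling to zero immediately outside
#' the window, so a single-bin spike has width 1.
#'
#' @param curve a `clip_curve`, or any data.frame with `offset` and `count`
#'   (or `fraction`) columns.
#' @return Width in nucleotides (double).
#' @export
fwhm <- function(curve) {
  y <- if (!is.null(curve$count)) as.numeric(curve$count) else
    as.numeric(curve$fraction)
  x <- as.numeric(curve$offset)
  if (!length(y) || max(y) <= 0) stop("fwhm undefined: curve has no positive maximum")
  # implicit zeros just outside the window
  x <- c(x[1L] - 1, x, x[length(x)] + 1)
  y <- c(0, y, 0)
  half <- max(y) / 2
  above <- y >= half
  up <- which(!above[-length(above)] & above[-1L])      # upward crossings
  down <- which(above[-length(above)] & !above[-1L])    # downward crossings
  if (length(up) + length(down) > 2L)
    warning("half-maximum crossed more than twice; using outermost crossings")
  i <- up[1L]
  left <- x[i] + (half - y[i]) / (y[i + 1L] - y[i]) * (x[i + 1L] - x[i])
  j <- down[length(down)]
  right <- x[j] + (y[j] - half) / (y[j] - y[j + 1L]) * (x[j + 1L] - x[j])
  right - left
}
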