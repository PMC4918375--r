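# shared in-code fixtures: tiny libraries, brute-force oracles

# random single-block fragment table on a small two-chromosome genome
random_fragments <- function(n, seed, chroms = c("chr1", "chr2"),
                             span = 3000L, len_range = c(18L, 40L),
                             groups = c("A", "B")) {
  withr::with_seed(seed, {
    len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    start <- sample.int(span - max(len), n, replace = TRUE)
    clip_fragments(
      chrom = sample(chroms, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      starts = start, ends = start + len,
      group = sample(groups, n, replace = TRUE),
      barcode = replicate(n, paste0(sample(c("A", "C", "G", "T"), 5L,
                                           replace = TRUE), collapse = "")),
      mapq = 40L)
  })
}

# brute-force overlap heatmap: triple loop over segments, references, queries
brute_overlap <- function(frags, config) {
  W <- config$offset_window
  spos <- anchor_positions(frags, "start")
  mpos <- anchor_positions(frags, config$anchor)
  seg <- paste(frags$chrom, frags$strand, spos %/% config$segment_size)
  keep_seg <- names(which(table(seg) >= config$min_reads))
  rmask <- if (identical(config$reference, "B")) frags$group == "B" else {
    hasAB <- any(frags$group == "A") && any(frags$group == "B")
    inr <- frags$length >= config$reference[1] & frags$length <= config$reference[2]
    if (hasAB) inr & frags$group == "A" else inr
  }
  hasAB <- any(frags$group == "A") && any(frags$group == "B")
  qmask <- if (config$query == "A" || (config$query == "auto" && hasAB))
    frags$group == "A" else rep(TRUE, nrow(frags))
  counts <- list()
  for (s in keep_seg) {
    inseg <- seg == s
    rp <- mpos[inseg & rmask]
    if (config$distinct_reference_positions) rp <- unique(rp)
    qi <- which(inseg & qmask)
    for (r in rp) for (q in qi) {
      off <- if (frags$strand[q] == "+") mpos[q] - r else r - mpos[q]
      if (abs(off) <= W) {
        key <- paste(frags$length[q], off)
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# compare a clip_overlap against the brute-force count list
overlap_matches_oracle <- function(hm, oracle) {
  dense <- hm$counts
  got <- list()
  for (i in seq_len(nrow(dense))) for (j in seq_len(ncol(dense)))
    if (dense[i, j] > 0)
      got[[paste(rownames(dense)[i], colnames(dense)[j])]] <- dense[i, j]
  if (!length(got) || !length(oracle))
    return(length(got) == length(oracle))
  identical(got[order(names(got))],
            lapply(oracle, as.integer)[order(names(oracle))])
}

# two-exon toy annotation on both strands
toy_exons <- function() {
  data.frame(
    chrom = "chr1",
    strand = c("+", "+", "-", "-"),
    start = c(100L, 300L, 1100L, 1300L),
    end = c(200L, 400L, 1200L, 1400L),
    transcript_id = c("tp", "tp", "tm", "tm"),
    stringsAsFactors = FALSE)
}
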