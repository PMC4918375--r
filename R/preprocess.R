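#' Describe the barcode layout at the 5' end of iCLIP reads
#'
#' iCLIP reads begin with an experiment (sample) barcode interleaved with
#' random barcode (UMI) bases. The layout string uses `N` for random
#' positions and `S` for sample positions, read 5' to 3'; dashes are
#' cosmetic. The default `NNN-SSSS-NN` (3 random + 4 sample + 2 random) is
#' the common iCLIP scheme.
#'
#' @param sample_barcodes character vector of expected sample barcodes,
#'   each as long as the number of `S` positions.
#' @param layout layout string over `N`/`S` (dashes ignored).
#' @param max_mismatches maximum Hamming distance allowed when matching the
#'   sample segment against `sample_barcodes`.
#' @return A list of class `barcode_scheme`.
#' @export
barcode_scheme <- function(sample_barcodes, layout = "NNN-SSSS-NN",
                           max_mismatches = 1L) {
  tpl <- strsplit(gsub("-", "", layout), "")[[1]]
  if (!all(tpl %in% c("N", "S"))) stop("layout may contain only N, S and dashes")
  ns <- sum(tpl == "S")
  if (!all(nchar(sample_barcodes) == ns))
    stop("every sample barcode must have length ", ns)
  if (!all(grepl("^[ACGTN]+$", sample_barcodes)))
    stop("sample barcodes may contain only A/C/G/T/N")
  structure(list(template = tpl, width = length(tpl),
                 sample_pos = which(tpl == "S"),
                 random_pos = which(tpl == "N"),
                 sample_barcodes = toupper(sample_barcodes),
                 max_mismatches = as.integer(max_mismatches)),
            class = "barcode_scheme")
}

#' Read / write FASTQ as a plain reads table
#'
#' Reads are kept as a data.frame with columns `id`, `sequence`, `quality`
#' (plus whatever annotation downstream steps add); parsing and writing go
#' through Biostrings.
#'
#' @param path FASTQ file (gzip allowed on input).
#' @return `read_fastq`: data.frame with `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @param reads data.frame with `id`, `sequence`, `quality` columns. If
#'   `barcode`/`group` columns are present they are folded into the read id
#'   as `id#BC:<barcode>#GR:<group>` so that they survive external mapping.
#' @export
write_fastq <- function(reads, path) {
  ids <- reads$id
  if (!is.null(reads$barcode)) ids <- paste0(ids, "#BC:", reads$barcode)
  if (!is.null(reads$group)) ids <- paste0(ids, "#GR:", reads$group)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

.hamming <- function(a, b) {
  # a: character vector, b: single string of equal width
  av <- strsplit(a, "")
  bv <- strsplit(b, "")[[1]]
  vapply(av, function(x) sum(x != bv), integer(1))
}

#' Demultiplex reads by sample barcode and extract random barcodes
#'
#' Splits the barcode prefix of each read according to the scheme layout,
#' assigns the read to the unique sample barcode within
#' `scheme$max_mismatches` of its sample segment, stores the concatenated
#' random-barcode bases in a `barcode` column, and strips the whole prefix
#' from sequence and qualities. Reads with no match, or with a tie at the
#' minimal mismatch count, go to the `undetermined` stream.
#'
#' @param reads data.frame from [read_fastq()].
#' @param scheme a [barcode_scheme()].
#' @return A list with one reads data.frame per sample barcode, an
#'   `undetermined` data.frame, and a `summary` count table.
#' @export
demultiplex <- function(reads, scheme) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  w <- scheme$width
  if (any(nchar(reads$sequence) <= w))
    stop("all reads must be longer than the barcode layout (", w, " nt)")
  prefix <- substr(reads$sequence, 1L, w)
  pm <- do.call(rbind, strsplit(prefix, ""))
  samp <- apply(pm[, scheme$sample_pos, drop = FALSE], 1L, paste0, collapse = "")
  rand <- apply(pm[, scheme$random_pos, drop = FALSE], 1L, paste0, collapse = "")
  d <- vapply(scheme$sample_barcodes, function(b) .hamming(samp, b),
              integer(nrow(reads)))
  d <- matrix(d, nrow = nrow(reads))
  best <- apply(d, 1L, min)
  nbest <- rowSums(d == best)
  hit <- max.col(-d, ties.method = "first")
  assigned <- best <= scheme$max_mismatches & nbest == 1L
  stripped <- reads
  stripped$sequence <- substr(reads$sequence, w + 1L, nchar(reads$sequence))
  stripped$quality <- substr(reads$quality, w + 1L, nchar(reads$quality))
  stripped$sample_barcode <- scheme$sample_barcodes[hit]
  stripped$barcode <- rand
  out <- lapply(seq_along(scheme$sample_barcodes), function(k) {
    r <- stripped[assigned & hit == k, , drop = FALSE]
    rownames(r) <- NULL
    r
  })
  names(out) <- scheme$sample_barcodes
  und <- reads[!assigned, , drop = FALSE]
  rownames(und) <- NULL
  n_amb <- sum(best <= scheme$max_mismatches & nbest > 1L)
  out$undetermined <- und
  out$summary <- data.frame(
    stream = c(scheme$sample_barcodes, "undetermined", "ambiguous"),
    reads = c(vapply(seq_along(scheme$sample_barcodes),
                     function(k) sum(assigned & hit == k), integer(1)),
              nrow(und), n_amb))
  out
}

# leftmost position (1-based) at which a prefix of `adapter` of length
# >= min_overlap matches the read suffix; NA if none
.adapter_hit <- function(seqs, adapter, min_overlap, max_mismatches) {
  n <- length(seqs)
  rl <- nchar(seqs)
  hit <- rep(NA_integer_, n)
  maxlen <- max(rl)
  al <- nchar(adapter)
  for (p in seq_len(maxlen)) {
    open <- which(is.na(hit) & rl - p + 1L >= min_overlap)
    if (!length(open)) break
    ov <- pmin(rl[open] - p + 1L, al)
    frag <- substr(seqs[open], p, p + ov - 1L)
    apre <- substr(rep(adapter, length(open)), 1L, ov)
    if (max_mismatches == 0L) {
      ok <- frag == apre
    } else {
      ok <- mapply(function(a, b) {
        sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) <= max_mismatches
      }, frag, apre, USE.NAMES = FALSE)
    }
    hit[open[ok]] <- p
  }
  hit
}

#' Trim the 3' adapter and classify reads into groups A and B
#'
#' Searches the 3' end of each read for a prefix of the 3' Solexa/Illumina
#' adapter (suffix-prefix overlap of at least `min_overlap` bases; exact
#' matching by default). Reads with a hit are trimmed at the match start and
#' labelled group `A`: the remaining insert is the complete fragment, so its
#' length is the true fragment length. Reads without a hit are labelled
#' group `B`: the fragment is at least as long as the read, so the insert
#' length is only a lower bound. Bases upstream of the match point are never
#' altered. Inserts shorter than `min_insert` after trimming are discarded
#' and counted.
#'
#' @param reads data.frame with at least `id`, `sequence`, `quality`.
#' @param adapter adapter sequence (5' end of it is what appears in reads).
#' @param min_overlap minimal adapter prefix length that counts as a hit.
#' @param max_mismatches mismatches tolerated inside the matched overlap.
#' @param min_insert minimal insert length kept after trimming.
#' @return The reads data.frame with columns `group` and `insert_length`,
#'   trimmed `sequence`/`quality`, and attributes `n_discarded`, `n_in`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L,
                         max_mismatches = 0L, min_insert = 15L) {
  stopifnot(nchar(adapter) >= min_overlap, min_overlap >= 1L)
  hit <- .adapter_hit(reads$sequence, toupper(adapter),
                      as.integer(min_overlap), as.integer(max_mismatches))
  grp <- ifelse(is.na(hit), "B", "A")
  ins_len <- ifelse(is.na(hit), nchar(reads$sequence), hit - 1L)
  out <- reads
  out$sequence <- substr(reads$sequence, 1L, ins_len)
  out$quality <- substr(reads$quality, 1L, ins_len)
  out$group <- grp
  out$insert_length <- as.integer(ins_len)
  keep <- out$insert_length >= min_insert
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_in") <- nrow(reads)
  attr(res, "n_discarded") <- sum(!keep)
  res
}
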