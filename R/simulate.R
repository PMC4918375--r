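#' Configuration of the mechanistic iCLIP library simulator
#'
#' The simulator draws, per cDNA molecule: a crosslink site; an RNA fragment
#' containing it, with boundaries kept out of a protein footprint and
#' optionally biased by an RNase cut-site base preference; a reverse
#' transcription outcome (truncation at the crosslink versus read-through to
#' the fragment 5' end); sequencing of `read_length` nt (shorter cDNAs run
#' into the 3' adapter and become group A); and PCR duplication. Every read
#' has a ground-truth row.
#'
#' Fragment boundaries sit outside the footprint `crosslink + footprint[1]
#' .. crosslink + footprint[2]` at geometric distances with mean
#' `digestion_mean` (capped at `digestion_max`); with `digestion =
#' "symmetric"` the 5' and 3' distances are equal per molecule, modelling a
#' protein that shields its footprint while digestion proceeds evenly on
#' both sides, which places fragment centres exactly on the crosslink under
#' read-through.
#'
#' @param n_genes,exons_per_gene,exon_width,intron_width,gene_spacing
#'   synthetic gene layout (alternating strands along one chromosome).
#' @param gc genome GC fraction.
#' @param crosslink_model `"fixed_offset"` (one site per exon-exon junction
#'   at `crosslink_offset`), `"motif_T"` (T positions 1-100 nt upstream of
#'   junctions, emulating the uridine preference of UV crosslinking) or
#'   `"uniform"` (uniform over transcript interiors).
#' @param crosslink_offset signed transcript-orientation offset of
#'   fixed-offset sites from the 5'ss junction (default -24, the EJC
#'   deposition site).
#' @param truncation_prob probability that reverse transcription truncates
#'   at the crosslink.
#' @param footprint protected interval around the crosslink, as
#'   `c(a, b)` relative offsets, or `NULL` for no protection.
#' @param digestion `"symmetric"` or `"independent"` boundary distances.
#' @param digestion_mean,digestion_max geometric mean / cap of the cut
#'   distance beyond the footprint edge, nt.
#' @param rnase_bias optional named weights `c(A=,C=,G=,T=)` for the base at
#'   the cut site (fragment start base and the base after the fragment
#'   end); boundaries are rejection-sampled against them.
#' @param read_length effective post-barcode read length, nt.
#' @param adapter 3' adapter sequence appended after short cDNAs.
#' @param min_overlap adapter bases that must fit on the read for it to be
#'   classified group A (mirrors [trim_adapter()]).
#' @param n_reads reads to emit (after PCR duplication).
#' @param pcr_dup_rate probability that an emitted read is a PCR copy of an
#'   already-emitted molecule.
#' @param barcode_layout,sample_barcode barcode scheme for the FASTQ path.
#' @param mapq alignment quality assigned to simulated fragments.
#' @param seed integer seed; all outputs are reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 12L, exons_per_gene = 3L, exon_width = 300L,
                       intron_width = 400L, gene_spacing = 800L, gc = 0.5,
                       crosslink_model = c("fixed_offset", "motif_T", "uniform"),
                       crosslink_offset = -24L, truncation_prob = 0.5,
                       footprint = c(-6L, 6L),
                       digestion = c("symmetric", "independent"),
                       digestion_mean = 20, digestion_max = 150L,
                       rnase_bias = NULL, read_length = 41L,
                       adapter = "AGATCGGAAGAGCGGTTCAG", min_overlap = 5L,
                       n_reads = 10000L, pcr_dup_rate = 0,
                       barcode_layout = "NNN-SSSS-NN", sample_barcode = "ACTG",
                       mapq = 40L, seed = 1L) {
  crosslink_model <- match.arg(crosslink_model)
  digestion <- match.arg(digestion)
  stopifnot(truncation_prob >= 0, truncation_prob <= 1,
            pcr_dup_rate >= 0, pcr_dup_rate < 1, gc > 0, gc < 1)
  if (!is.null(footprint)) {
    stopifnot(length(footprint) == 2L, footprint[1L] < footprint[2L])
    if (diff(footprint) + 1L > digestion_max)
      stop("footprint wider than the maximal fragment extent")
  }
  if (!is.null(rnase_bias))
    stopifnot(all(c("A", "C", "G", "T") %in% names(rnase_bias)),
              all(rnase_bias > 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Presets for the three mechanistic regimes
#'
#' `"truncation"`: reverse transcription truncates at the crosslink for 90%
#' of molecules (coinciding start sites, the U2AF65-type regime);
#' `"readthrough"`: 10% truncation (non-coinciding start sites, the
#' eIF4A3-type regime); `"footprint"`: pure read-through with the protein
#' footprint as the only structure. All three keep the 13-nt footprint on
#' and symmetric digestion.
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @param n_reads reads to emit.
#' @param ... further overrides passed to [sim_config()].
#' @export
sim_preset <- function(preset = c("truncation", "readthrough", "footprint"),
                       seed = 1L, n_reads = 50000L, ...) {
  preset <- match.arg(preset)
  p <- switch(preset, truncation = 0.9, readthrough = 0.1, footprint = 0)
  sim_config(truncation_prob = p, seed = seed, n_reads = n_reads, ...)
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a genome with gene models
#'
#' Generates a random genome at the configured GC content and lays
#' `n_genes` multi-exon genes along it on alternating strands. Deterministic
#' per seed.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_genome`: `genome` (DNAStringSet, one
#'   chromosome `chr1`), `exons` (data.frame, 0-based half-open),
#'   `catalog` (junction catalog), `transcripts` (per-transcript exon
#'   structures, transcript-coordinate maps and spliced sequences).
#' @export
simulate_genome <- function(config) {
  .with_seed(config$seed, {
    gene_span <- config$exons_per_gene * config$exon_width +
      (config$exons_per_gene - 1L) * config$intron_width
    stride <- gene_span + config$gene_spacing
    glen <- config$n_genes * stride + config$gene_spacing
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    seqchr <- paste(sample(names(p), glen, replace = TRUE, prob = p),
                    collapse = "")
    genome <- Biostrings::DNAStringSet(seqchr)
    names(genome) <- "chr1"
    exons <- do.call(rbind, lapply(seq_len(config$n_genes), function(g) {
      g0 <- config$gene_spacing %/% 2L + (g - 1L) * stride
      es <- g0 + (seq_len(config$exons_per_gene) - 1L) *
        (config$exon_width + config$intron_width)
      data.frame(chrom = "chr1",
                 strand = if (g %% 2L == 1L) "+" else "-",
                 start = es, end = es + config$exon_width,
                 gene_id = sprintf("g%02d", g),
                 transcript_id = sprintf("t%02d", g),
                 exon_number = seq_along(es), stringsAsFactors = FALSE)
    }))
    if (max(exons$end) > glen) stop("gene models exceed the genome")
    transcripts <- .build_transcripts(exons, genome)
    structure(list(genome = genome, exons = exons,
                   catalog = junction_catalog_from_exons(exons),
                   transcripts = transcripts, config = config),
              class = "sim_genome")
  })
}

# per-transcript structure: exons in transcript (5'->3') order with
# cumulative transcript starts, plus the spliced sequence
.build_transcripts <- function(exons, genome) {
  out <- lapply(split(exons, exons$transcript_id), function(e) {
    e <- e[order(e$start), ]
    strand <- e$strand[1L]
    if (strand == "-") e <- e[rev(seq_len(nrow(e))), ]
    w <- e$end - e$start
    cum <- cumsum(c(0L, w))[seq_len(nrow(e))]
    pieces <- Biostrings::extractAt(
      genome[[e$chrom[1L]]],
      IRanges::IRanges(sort(e$start) + 1L, sort(e$end)))
    seq <- Biostrings::DNAString(paste0(as.character(pieces), collapse = ""))
    if (strand == "-") seq <- Biostrings::reverseComplement(seq)
    list(chrom = e$chrom[1L], strand = strand,
         gstart = e$start, gend = e$end,      # transcript order
         cum = cum, txlen = sum(w),
         junctions_t = if (nrow(e) > 1L) cum[-1L] else integer(),
         seq = as.character(seq))
  })
  out
}

# genomic position of transcript coordinate t (scalar tx, vector t)
.tx2genome_point <- function(tx, t) {
  j <- findInterval(t, tx$cum)
  o <- t - tx$cum[j]
  ifelse(tx$strand == "+", tx$gstart[j] + o, tx$gend[j] - 1L - o)
}

# genomic blocks (0-based half-open, ascending) of transcript interval
# [t5, t3] inclusive
.tx2genome_blocks <- function(tx, t5, t3) {
  j5 <- findInterval(t5, tx$cum)
  j3 <- findInterval(t3, tx$cum)
  ks <- j5:j3
  a <- pmax(t5, tx$cum[ks])
  b <- pmin(t3, c(tx$cum[-1L], tx$txlen)[ks] - 1L)
  if (tx$strand == "+") {
    s <- tx$gstart[ks] + (a - tx$cum[ks])
    e <- tx$gstart[ks] + (b - tx$cum[ks]) + 1L
  } else {
    s <- tx$gend[ks] - 1L - (b - tx$cum[ks])
    e <- tx$gend[ks] - (a - tx$cum[ks])
    o <- order(s)
    s <- s[o]; e <- e[o]
  }
  cbind(start = as.integer(s), end = as.integer(e))
}

# candidate crosslink sites as data.frame(tx, tpos); margin keeps fragments
# inside the transcript
.crosslink_sites <- function(sim, config) {
  margin <- config$digestion_max + 10L
  rows <- lapply(names(sim$transcripts), function(id) {
    tx <- sim$transcripts[[id]]
    tpos <- switch(config$crosslink_model,
      fixed_offset = tx$junctions_t + config$crosslink_offset,
      motif_T = {
        cand <- unlist(lapply(tx$junctions_t, function(j)
          seq(max(j - 100L, 0L), j - 1L)))
        cand <- unique(cand)
        cand[substring(tx$seq, cand + 1L, cand + 1L) == "T"]
      },
      uniform = seq(margin, tx$txlen - margin - 1L))
    tpos <- tpos[tpos >= margin & tpos <= tx$txlen - margin - 1L]
    if (!length(tpos)) return(NULL)
    data.frame(tx = id, tpos = as.integer(tpos), stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, rows)
  if (is.null(sites) || !nrow(sites))
    stop("no usable crosslink sites; enlarge exons or reduce digestion_max")
  sites
}

.draw_cut <- function(n, config) {
  pmin(stats::rgeom(n, 1 / (config$digestion_mean + 1)),
       config$digestion_max)
}

#' Simulate an iCLIP library with ground truth
#'
#' Emits the library as an aligned fragment table (the observed, possibly
#' read-length-censored cDNA of every read, projected through the exon
#' structure into genomic blocks) plus a per-read truth table. Use
#' [simulate_fastq()] for raw reads and [write_sam()] for alignments when a
#' full-stack run through [trim_adapter()] / [load_fragments()] is wanted.
#'
#' @param config a [sim_config()].
#' @param sim a [simulate_genome()] result for the same config.
#' @return A list of class `sim_library`: `fragments` ([clip_fragments],
#'   one row per read, duplicates included) and `truth` (data.frame with
#'   per-read crosslink, fragment interval, mechanism, group, barcode and
#'   PCR provenance).
#' @export
simulate_library <- function(config, sim) {
  .with_seed(config$seed + 1L, {
    sites <- .crosslink_sites(sim, config)
    n <- config$n_reads
    # PCR: molecule k is emitted 1 + Geom(1 - dup_rate) times
    copies <- integer(0)
    while (sum(copies) < n) {
      k <- max(64L, ceiling((n - sum(copies)) * (1 - config$pcr_dup_rate)))
      copies <- c(copies, 1L + stats::rgeom(k, 1 - config$pcr_dup_rate))
    }
    K <- which(cumsum(copies) >= n)[1L]
    copies <- copies[seq_len(K)]
    copies[K] <- copies[K] - (sum(copies) - n)

    si <- sample.int(nrow(sites), K, replace = TRUE)
    txid <- sites$tx[si]
    tpos <- sites$tpos[si]
    txlen <- vapply(sim$transcripts[txid], `[[`, integer(1), "txlen")

    if (config$digestion == "symmetric") {
      u5 <- u3 <- .draw_cut(K, config)
    } else {
      u5 <- .draw_cut(K, config)
      u3 <- .draw_cut(K, config)
    }
    if (is.null(config$footprint)) {
      fa <- -1L; fb <- 1L      # crosslink strictly interior to the fragment
    } else {
      fa <- config$footprint[1L]; fb <- config$footprint[2L]
    }
    frag_t5 <- tpos + fa - 1L - u5
    frag_t3 <- tpos + fb + 1L + u3
    if (!is.null(config$rnase_bias)) {
      w <- config$rnase_bias / max(config$rnase_bias)
      seqs <- vapply(sim$transcripts[txid], `[[`, character(1), "seq")
      for (try in 1:25) {
        b5 <- substring(seqs, frag_t5 + 1L, frag_t5 + 1L)
        bad5 <- stats::runif(K) > w[b5] & frag_t5 > 0L
        if (any(bad5))
          frag_t5[bad5] <- tpos[bad5] + fa - 1L - .draw_cut(sum(bad5), config)
        b3 <- substring(seqs, frag_t3 + 2L, frag_t3 + 2L)
        bad3 <- stats::runif(K) > w[b3] & frag_t3 < txlen - 2L
        if (any(bad3))
          frag_t3[bad3] <- tpos[bad3] + fb + 1L + .draw_cut(sum(bad3), config)
        if (!any(bad5) && !any(bad3)) break
      }
    }
    frag_t5 <- pmax(frag_t5, 0L)
    frag_t3 <- pmin(frag_t3, txlen - 1L)

    truncated <- stats::runif(K) < config$truncation_prob
    cdna_t5 <- ifelse(truncated, tpos + 1L, frag_t5)
    clen <- frag_t3 - cdna_t5 + 1L
    grp <- ifelse(config$read_length - clen >= config$min_overlap, "A", "B")
    obs_len <- ifelse(grp == "A", clen, pmin(clen, config$read_length))
    obs_t3 <- cdna_t5 + obs_len - 1L

    strand <- vapply(sim$transcripts[txid], `[[`, character(1), "strand")
    chrom <- vapply(sim$transcripts[txid], `[[`, character(1), "chrom")
    nN <- sum(strsplit(gsub("-", "", config$barcode_layout), "")[[1]] == "N")
    bc <- apply(matrix(sample(c("A", "C", "G", "T"), K * nN, replace = TRUE),
                       K), 1L, paste0, collapse = "")

    bl <- vector("list", K)
    gx <- integer(K); g5 <- integer(K)
    for (k in seq_len(K)) {
      tx <- sim$transcripts[[txid[k]]]
      bl[[k]] <- .tx2genome_blocks(tx, cdna_t5[k], obs_t3[k])
      gx[k] <- .tx2genome_point(tx, tpos[k])
      g5[k] <- .tx2genome_point(tx, cdna_t5[k])
    }

    rd <- rep(seq_len(K), times = copies)
    frags <- clip_fragments(
      chrom = chrom[rd], strand = strand[rd],
      starts = lapply(bl[rd], function(b) b[, 1L]),
      ends = lapply(bl[rd], function(b) b[, 2L]),
      group = grp[rd], barcode = bc[rd], mapq = config$mapq)
    first <- !duplicated(rd)
    truth <- data.frame(
      read_id = sprintf("sim%06d", seq_len(n)),
      molecule = rd,
      duplicate_of = ifelse(first, NA_character_,
                            sprintf("sim%06d", match(rd, rd))),
      transcript = txid[rd], chrom = chrom[rd], strand = strand[rd],
      crosslink_t = tpos[rd], crosslink_g = gx[rd],
      frag_t5 = frag_t5[rd], frag_t3 = frag_t3[rd],
      cdna_t5 = cdna_t5[rd], cdna_len = clen[rd], obs_len = obs_len[rd],
      cdna_g5 = g5[rd],
      mechanism = ifelse(truncated[rd], "truncated", "read_through"),
      group = grp[rd], barcode = bc[rd], stringsAsFactors = FALSE)
    structure(list(fragments = frags, truth = truth, config = config),
              class = "sim_library")
  })
}

#' Raw FASTQ reads for a simulated library
#'
#' Rebuilds each read from first principles: the full cDNA sequence (not the
#' censored observation), followed by the 3' adapter and `A` padding up to
#' the read length, with the barcode prefix laid out per the configured
#' scheme. Feeding these reads through [demultiplex()] and [trim_adapter()]
#' reproduces the library's group labels and insert lengths.
#'
#' @param lib a [simulate_library()] result.
#' @param sim the matching [simulate_genome()] result.
#' @return data.frame with `id`, `sequence`, `quality` (read ids match the
#'   truth table).
#' @export
simulate_fastq <- function(lib, sim) {
  config <- lib$config
  tr <- lib$truth
  seqs <- vapply(sim$transcripts[tr$transcript], `[[`, character(1), "seq")
  insert <- substring(seqs, tr$cdna_t5 + 1L, tr$cdna_t5 + tr$cdna_len)
  tail <- paste0(config$adapter, strrep("A", config$read_length))
  body <- substr(paste0(insert, tail), 1L, config$read_length)
  tpl <- strsplit(gsub("-", "", config$barcode_layout), "")[[1]]
  sbc <- strsplit(config$sample_barcode, "")[[1]]
  pre <- vapply(tr$barcode, function(rb) {
    ch <- character(length(tpl))
    ch[tpl == "N"] <- strsplit(rb, "")[[1]]
    ch[tpl == "S"] <- sbc
    paste0(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  sequence <- paste0(pre, body)
  data.frame(id = tr$read_id, sequence = sequence,
             quality = strrep("I", nchar(sequence)),
             stringsAsFactors = FALSE)
}

#' Write simulated genome and annotation to FASTA + GTF
#'
#' @param sim a [simulate_genome()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector with the `fasta` and `gtf` paths.
#' @export
write_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "genes.gtf")
  Biostrings::writeXStringSet(sim$genome, fa)
  write_gtf(sim$exons, gtf)
  c(fasta = fa, gtf = gtf)
}

#' Write a fragment table as SAM
#'
#' Each fragment becomes one primary alignment; spliced fragments get
#' `M`/`N` CIGARs; the random barcode and adapter group travel in the read
#' name as `id#BC:<barcode>#GR:<group>`, the convention [load_fragments()]
#' expects. Sequences are omitted (`*`), as only coordinates matter here.
#'
#' @param frags a [clip_fragments] table.
#' @param seqlengths named integer vector of chromosome lengths (or a
#'   `sim_genome`, whose genome widths are used).
#' @param path output `.sam` path.
#' @param ids optional read names (default `rd<row>`).
#' @export
write_sam <- function(frags, seqlengths, path, ids = NULL) {
  if (inherits(seqlengths, "sim_genome"))
    seqlengths <- stats::setNames(Biostrings::width(seqlengths$genome),
                                  names(seqlengths$genome))
  if (is.null(ids)) ids <- sprintf("rd%06d", seq_len(nrow(frags)))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), seqlengths))
  cigar <- vapply(seq_len(nrow(frags)), function(i) {
    if (frags$nblocks[i] == 1L) {
      paste0(frags$length[i], "M")
    } else {
      b <- frags$blocks[[i]]
      m <- b[, 2L] - b[, 1L]
      gaps <- b[-1L, 1L] - b[-nrow(b), 2L]
      paste0(paste0(m[-length(m)], "M", gaps, "N", collapse = ""),
             m[length(m)], "M")
    }
  }, character(1))
  rows <- sprintf("%s#BC:%s#GR:%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                  ids, frags$barcode, frags$group,
                  ifelse(frags$strand == "+", 0L, 16L),
                  frags$chrom, frags$gstart + 1L, frags$mapq, cigar)
  o <- order(frags$chrom, frags$gstart)
  writeLines(c(hdr, rows[o]), path)
  invisible(path)
}
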