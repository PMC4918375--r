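test_that("demultiplex slices the barcode layout and routes reads", {
  sch <- barcode_scheme("TTTT", layout = "NNN-SSSS-NN", max_mismatches = 1)
  reads <- data.frame(
    id = c("r1", "r2", "r3"),
    sequence = c(
      "ACGTTTTGGCCCAAACCC",   # exact sample match
      "ACGTATTGGCCCAAACCC",   # 1 mismatch -> still assigned
      "ACGAAAAGGCCCAAACCC"),  # 4 mismatches -> undetermined
    quality = strrep("I", 18))
  dm <- demultiplex(reads, sch)
  expect_equal(dm$TTTT$id, c("r1", "r2"))
  expect_equal(dm$TTTT$barcode, c("ACGGG", "ACGGG"))
  expect_equal(dm$TTTT$sequence, c("CCCAAACCC", "CCCAAACCC"))
  expect_equal(dm$undetermined$id, "r3")
  expect_equal(dm$summary$reads[dm$summary$stream == "TTTT"], 2)
})

test_that("ambiguous barcode assignments go to undetermined", {
  sch <- barcode_scheme(c("TTTT", "TTTA"), max_mismatches = 1)
  # sample segment TTTG is 1 mismatch from both -> tie -> undetermined
  reads <- data.frame(id = "r1", sequence = "ACGTTTGGGCCCAAACCC",
                      quality = strrep("I", 18))
  dm <- demultiplex(reads, sch)
  expect_equal(nrow(dm$undetermined), 1L)
  expect_equal(dm$summary$reads[dm$summary$stream == "ambiguous"], 1)
})

test_that("unique best hit within max_mismatches matches a Hamming scan", {
  set.seed(41)
  barcodes <- c("AACC", "GGTT", "CAGT")
  sch <- barcode_scheme(barcodes, max_mismatches = 1)
  for (i in 1:50) {
    samp <- paste0(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                   collapse = "")
    read <- data.frame(id = "r", quality = strrep("I", 20),
                       sequence = paste0("AAA", samp, "GG", strrep("C", 11)))
    dm <- demultiplex(read, sch)
    d <- sapply(barcodes, function(b)
      sum(strsplit(samp, "")[[1]] != strsplit(b, "")[[1]]))
    expected <- if (min(d) <= 1 && sum(d == min(d)) == 1)
      barcodes[which.min(d)] else "undetermined"
    assigned <- names(which(sapply(dm[barcodes], nrow) == 1))
    got <- if (length(assigned)) assigned else "undetermined"
    expect_equal(got, expected)
  }
})

test_that("adapter trimming classifies groups and enforces min insert", {
  adapter <- "AGATCGGAAGAGC"
  reads <- data.frame(
    id = c("short", "noadapter", "partial"),
    sequence = c(
      paste0("AAAA", adapter),                          # insert 4 -> discarded
      strrep("G", 40),                                  # group B, length 40
      paste0(strrep("G", 32), substr(adapter, 1, 8))),  # 8 nt overlap -> A, 32
    quality = c(strrep("I", 4 + nchar(adapter)), strrep("I", 40),
                strrep("I", 40)))
  out <- trim_adapter(reads, adapter, min_overlap = 5)
  expect_equal(attr(out, "n_discarded"), 1L)
  expect_equal(out$group, c("B", "A"))
  expect_equal(out$insert_length, c(40L, 32L))
  expect_equal(out$sequence[2], strrep("G", 32))
})

test_that("trimming never alters bases upstream of the match point", {
  adapter <- "AGATCGGAAGAGC"
  set.seed(7)
  for (i in 1:20) {
    ins <- paste0(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                  collapse = "")
    read <- data.frame(id = "r", sequence = paste0(ins, adapter),
                       quality = strrep("I", 25 + nchar(adapter)))
    out <- trim_adapter(read, adapter)
    expect_equal(out$group, "A")
    expect_equal(out$sequence, ins)
  }
})

test_that("every kept read is in exactly one group and counts add up", {
  cfg <- sim_config(n_reads = 400, seed = 21, truncation_prob = 0.5)
  sim <- simulate_genome(cfg)
  lib <- simulate_library(cfg, sim)
  fq <- simulate_fastq(lib, sim)
  dm <- demultiplex(fq, barcode_scheme(cfg$sample_barcode, cfg$barcode_layout))
  tr <- trim_adapter(dm[[cfg$sample_barcode]], cfg$adapter,
                     min_overlap = cfg$min_overlap)
  expect_true(all(tr$group %in% c("A", "B")))
  expect_equal(nrow(tr) + attr(tr, "n_discarded"), nrow(fq))
})

test_that("SAM alignments load with CIGAR blocks and MAPQ filter", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    "r1#BC:ACGTA#GR:A\t0\tchr1\t101\t40\t36M\t*\t0\t0\t*\t*",
    "r2#BC:ACGTA#GR:B\t0\tchr1\t101\t40\t20M200N16M\t*\t0\t0\t*\t*",
    "r3#BC:ACGTA#GR:A\t16\tchr1\t201\t9\t30M\t*\t0\t0\t*\t*"), sam)
  fr <- load_fragments(sam, min_mapq = 10)
  expect_equal(nrow(fr), 2L)                 # MAPQ 9 record excluded
  expect_equal(attr(fr, "n_low_mapq"), 1L)
  expect_equal(fr$gstart, c(100L, 100L))
  expect_equal(fr$length, c(36L, 36L))
  expect_equal(fr$nblocks, c(1L, 2L))
  expect_equal(fr$blocks[[2]],
               cbind(start = c(100L, 320L), end = c(120L, 336L)))
  expect_equal(fr$group, c("A", "B"))
})

test_that("reads without barcode annotation are a hard error", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:chr1\tLN:10000",
               "anon\t0\tchr1\t101\t40\t36M\t*\t0\t0\t*\t*"), sam)
  expect_error(load_fragments(sam), "anon")
})

test_that("deduplication keeps one representative per position-barcode key", {
  fr <- clip_fragments(
    chrom = "chr1", strand = "+",
    starts = c(100L, 100L, 100L, 250L),
    ends = c(130L, 140L, 135L, 280L),
    group = "A",
    barcode = c("AAAAA", "AAAAA", "CCCCC", "AAAAA"))
  dd <- deduplicate(fr)
  expect_equal(nrow(dd), 3L)
  # same key (100, AAAAA): longest representative kept
  expect_equal(dd$gend[dd$barcode == "AAAAA" & dd$gstart == 100L], 140L)
  expect_equal(attr(dd, "n_removed"), 1L)
})

test_that("deduplication is idempotent and matches key counting", {
  for (s in 1:5) {
    fr <- random_fragments(300, seed = s, span = 500L)
    dd <- deduplicate(fr)
    keys <- paste(fr$chrom, fr$strand, anchor_positions(fr, "start"),
                  fr$barcode)
    expect_equal(nrow(dd), length(unique(keys)))
    dd2 <- deduplicate(dd)
    expect_equal(as.data.frame(dd2), as.data.frame(dd))
  }
})

test_that("group A fragment length equals the trimmed insert length", {
  cfg <- sim_config(n_reads = 300, seed = 31, truncation_prob = 0.6)
  sim <- simulate_genome(cfg)
  lib <- simulate_library(cfg, sim)
  fq <- simulate_fastq(lib, sim)
  dm <- demultiplex(fq, barcode_scheme(cfg$sample_barcode, cfg$barcode_layout))
  tr <- trim_adapter(dm[[cfg$sample_barcode]], cfg$adapter,
                     min_overlap = cfg$min_overlap, min_insert = 1)
  m <- match(tr$id, lib$truth$read_id)
  expect_equal(tr$group, lib$truth$group[m])
  ga <- tr$group == "A"
  expect_true(any(ga))
  expect_equal(tr$insert_length[ga], lib$truth$cdna_len[m][ga])
  expect_equal(tr$insert_length[ga], lib$fragments$length[m][ga])
})
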