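test_that("segment read-count threshold is exact", {
  mk <- function(n) {
    start <- as.integer(seq(10, 290, length.out = n))
    clip_fragments(chrom = "chr1", strand = "+", starts = start,
                   ends = start + 25L, group = "A")
  }
  cfg <- overlap_config(min_reads = 50)
  expect_equal(attr(segment_fragments(mk(50), cfg), "n_segments"), 1L)
  expect_warning(s49 <- segment_fragments(mk(49), cfg), "min_reads")
  expect_equal(attr(s49, "n_segments"), 0L)
})

test_that("fragments straddling a segment boundary are binned by start anchor", {
  # + strand fragment starting at 299 spans into the next segment
  # - strand fragment with gstart 295 has its start anchor at gend-1 = 314
  fr <- clip_fragments(chrom = "chr1", strand = c("+", "-"),
                       starts = c(299L, 295L), ends = c(330L, 315L))
  cfg <- overlap_config(min_reads = 1)
  sf <- segment_fragments(fr, cfg)
  expect_equal(sf$segment, c("chr1:+:0", "chr1:-:1"))
  # oracle: rebin every fragment by floor(start anchor / size)
  for (s in 1:3) {
    rf <- random_fragments(100, seed = s, span = 2000L)
    sf <- segment_fragments(rf, overlap_config(min_reads = 1))
    expect_equal(sf$segment,
                 paste0(rf$chrom, ":", rf$strand, ":",
                        anchor_positions(rf, "start") %/% 300L))
  }
})

test_that("reference selectors resolve groups, length ranges and multiplicity", {
  fr <- clip_fragments(chrom = "chr1", strand = "+",
                       starts = c(10L, 10L, 40L, 60L, 80L),
                       ends = c(42L, 42L, 72L, 96L, 118L),
                       group = c("B", "B", "B", "A", "A"))
  expect_equal(reference_positions(fr, overlap_config(reference = "B")),
               c(10L, 10L, 40L))
  cfgd <- overlap_config(reference = "B", distinct_reference_positions = TRUE)
  expect_equal(reference_positions(fr, cfgd), c(10L, 40L))
  # group A length range 33-39 keeps the 36/38-nt A fragments, excludes 32-nt
  expect_equal(fr$length, c(32L, 32L, 32L, 36L, 38L))
  expect_equal(reference_positions(fr, overlap_config(reference = c(33, 39))),
               c(60L, 80L))
  expect_equal(reference_positions(fr, overlap_config(reference = c(37, 39))),
               80L)
  expect_equal(reference_positions(fr, overlap_config(reference = c(33, 35))),
               integer(0))
})

test_that("offsets are recorded in transcript orientation", {
  # reference B start at 100 (+): query A at 107 -> +7
  frp <- clip_fragments(chrom = "chr1", strand = "+",
                        starts = c(100L, 107L), ends = c(145L, 137L),
                        group = c("B", "A"))
  cfg <- overlap_config(min_reads = 1)
  hm <- overlap_heatmap(frp, cfg)
  expect_equal(sum(hm$counts), 1L)
  expect_equal(hm$counts["30", "7"], 1L)
  # on -: reference start anchor 144, query start anchor 137, 7 nt downstream
  frm <- clip_fragments(chrom = "chr1", strand = "-",
                        starts = c(100L, 108L), ends = c(145L, 138L),
                        group = c("B", "A"))
  hmm <- overlap_heatmap(frm, cfg)
  expect_equal(hmm$counts["30", "7"], 1L)
  # exact coincidence lands at column 0
  fr0 <- clip_fragments(chrom = "chr1", strand = "+",
                        starts = c(100L, 100L), ends = c(145L, 130L),
                        group = c("B", "A"))
  hm0 <- overlap_heatmap(fr0, cfg)
  expect_equal(hm0$counts["30", "0"], 1L)
})

test_that("overlap heatmap equals the brute-force pairwise oracle", {
  for (s in 1:6) {
    fr <- random_fragments(40L + 10L * s, seed = 100 + s, span = 1500L)
    cfg <- overlap_config(min_reads = 5L, offset_window = 30L,
                          anchor = sample(c("start", "centre", "end"), 1))
    hm <- overlap_heatmap(fr, cfg)
    expect_true(overlap_matches_oracle(hm, brute_overlap(fr, cfg)))
    # and with distinct reference positions
    cfgd <- cfg; cfgd$distinct_reference_positions <- TRUE
    expect_true(overlap_matches_oracle(overlap_heatmap(fr, cfgd),
                                       brute_overlap(fr, cfgd)))
  }
})

test_that("a mirror-symmetric heatmap gives ratio 1 for every length", {
  counts <- matrix(0L, nrow = 3, ncol = 101,
                   dimnames = list(c(20, 25, 30), -50:50))
  withr::with_seed(8, {
    for (i in 1:3) {
      half <- rpois(50, 4)
      counts[i, ] <- c(rev(half), rpois(1, 4), half)
    }
  })
  rr <- ratio_from_heatmap(counts, overlap_config(read_length = 41))
  expect_equal(rr$per_length$ratio, rep(1, 3))
  expect_equal(rr$mean_ratio, 1)
  expect_equal(rr$verdict, "indeterminate")
})

test_that("ratio ranges honour the length-specific maximal offset and flank", {
  counts <- matrix(0L, nrow = 1, ncol = 101, dimnames = list(31, -50:50))
  # maxoff = floor((41-31)/2) = 5, flank 5 -> scan -10..-1 and 1..10
  counts[1, as.character(c(-11, 11))] <- 100L   # outside the range: ignored
  counts[1, as.character(-3)] <- 8L
  counts[1, as.character(c(2, 6))] <- c(3L, 1L)
  rr <- ratio_from_heatmap(counts, overlap_config(read_length = 41))
  expect_equal(rr$per_length$upstream_mean, 0.8)
  expect_equal(rr$per_length$downstream_mean, 0.4)
  expect_equal(rr$per_length$ratio, 2)
  # ceil rounding widens the range by one bin for odd read_length - L
  rrf <- ratio_from_heatmap(counts, overlap_config(read_length = 42))
  expect_equal(rrf$per_length$upstream_mean, 0.8)        # floor: still -10..-1
  rrc <- ratio_from_heatmap(counts, overlap_config(read_length = 42,
                                                   maxoff_rounding = "ceil"))
  expect_equal(rrc$per_length$upstream_mean, 108 / 11)   # -11 now included
  # offset 0 belongs to neither side
  counts[1, "0"] <- 1000L
  rr0 <- ratio_from_heatmap(counts, overlap_config(read_length = 41))
  expect_equal(rr0$per_length$ratio, 2)
})

test_that("lengths with empty downstream range are excluded, all-empty errors", {
  counts <- matrix(0L, nrow = 2, ncol = 101, dimnames = list(c(20, 30), -50:50))
  counts["20", as.character(-4)] <- 6L
  counts["30", as.character(c(-2, 3))] <- c(4L, 2L)
  rr <- ratio_from_heatmap(counts, overlap_config(read_length = 41))
  expect_equal(rr$n_lengths, 1L)
  expect_true(is.na(rr$per_length$ratio[rr$per_length$length == 20]))
  empty <- matrix(0L, nrow = 1, ncol = 101, dimnames = list(25, -50:50))
  expect_error(ratio_from_heatmap(empty, overlap_config(read_length = 41)),
               "undefined")
})

test_that("increasing truncation probability drives the ratio up", {
  for (s in 1:5) {
    mr <- sapply(c(0.1, 0.5, 0.9), function(tp) {
      cfg <- sim_config(truncation_prob = tp, n_reads = 6000, seed = 400 + s,
                        min_overlap = 5L)
      sim <- simulate_genome(cfg)
      dd <- deduplicate(simulate_library(cfg, sim)$fragments)
      start_site_overlap_ratio(
        dd, overlap_config(read_length = cfg$read_length,
                           min_reads = 20L))$mean_ratio
    })
    expect_true(all(diff(mr) > 0))
  }
})

test_that("group B and long group A references agree on the verdict", {
  for (p in c("truncation", "readthrough")) {
    cfg <- sim_preset(p, seed = 77, n_reads = 20000)
    sim <- simulate_genome(cfg)
    dd <- deduplicate(simulate_library(cfg, sim)$fragments)
    vb <- start_site_overlap_ratio(
      dd, overlap_config(reference = "B", read_length = cfg$read_length))
    va <- start_site_overlap_ratio(
      dd, overlap_config(reference = c(33, 39), read_length = cfg$read_length))
    expect_equal(vb$verdict, va$verdict)
    expect_equal(vb$verdict,
                 if (p == "truncation") "start_based" else "centre_based")
  }
})

test_that("HITS-CLIP mode falls back to all fragments as queries", {
  fr <- clip_fragments(chrom = "chr1", strand = "+",
                       starts = c(10L, 20L, 30L), ends = c(45L, 55L, 64L),
                       group = "A")   # no B fragments anywhere
  cfg <- overlap_config(min_reads = 1, reference = c(35, 36))
  hm <- overlap_heatmap(fr, cfg)
  # references: the two 35-nt fragments; queries: all three (lengths 35,35,34)
  expect_equal(hm$n_reference, 2L)
  expect_equal(hm$n_query, 3L)
})
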