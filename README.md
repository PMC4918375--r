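# iclipfrag

Fragment-length diagnostics and binding-site assignment for iCLIP.

## The problem

iCLIP assigns protein–RNA crosslink sites assuming that reverse
transcription truncates at the crosslinked nucleotide, so that the base
preceding each read start marks the binding site regardless of fragment
length. For several RNA-binding proteins that assumption does not hold:
read start sites spread upstream of the binding site in a
fragment-length-dependent way (read-through of the reverse transcriptase,
or crosslinking across a long footprint), and start-based analysis
misplaces and widens the assigned sites. In that regime the fragment
*centre* is the more accurate anchor.

`iclipfrag` is for analysts of iCLIP (and HITS-CLIP) libraries who need to
decide, per library, which anchor to trust. It provides:

* adapter-based classification of reads into completely sequenced
  fragments (**group A**, true length known) and length-censored fragments
  (**group B**);
* random-barcode (UMI) deduplication of aligned fragments;
* junction-anchored read distribution maps and length-stratified heatmaps
  with FWHM estimation;
* annotation-free **read overlap heatmaps** and the **start site overlap
  ratio**;
* base-composition matrices around fragment starts and ends;
* a mechanistic iCLIP library simulator with per-read ground truth
  (truncation vs read-through, RNase footprint protection, PCR
  duplication), so the whole pipeline is testable without any downloads.

## The core statistic

Within 300-nt genomic segments holding at least 50 deduplicated fragments,
the centre positions of reference fragments (group B by default, or group
A of 33–39 nt) define 0-positions. For every query fragment of length *L*,
the offset of its centre to every 0-position is recorded over −50..+50 nt.
If starts coincide, query centres sit upstream of the (read-length
censored) reference centres by at most *m(L)* = ⌊(*R* − *L*)/2⌋ for
effective read length *R*. The **start site overlap ratio** of length *L*
is the mean count per bin over [−(*m(L)*+5), −1] divided by the mean over
[+1, +(*m(L)*+5)]; the library report is the mean and median across
lengths. Mean ratio > 1: starts coincide, use start-based assignment
(crosslink = base before the read start). Mean ratio < 1: use fragment
centres.

## Worked example

Simulate a read-through-dominated library (10% truncation, 13-nt protein
footprint, crosslinks 24 nt upstream of exon–exon junctions), deduplicate,
and run the diagnostics:

```r
library(iclipfrag)

cfg  <- sim_preset("readthrough", seed = 42, n_reads = 20000)
sim  <- simulate_genome(cfg)
lib  <- simulate_library(cfg, sim)
frags <- deduplicate(lib$fragments)
frags
#> clip_fragments: 19762 fragments (8782 group A, 10980 group B, 861 spliced)

cv <- distribution_curve(frags, sim$catalog, anchor = "centre", junction = "5ss")
cv$offset[which.max(cv$count)]   # centre-anchored peak
#> [1] -24
fwhm(cv)
#> [1] 1

rr <- start_site_overlap_ratio(frags, overlap_config(read_length = cfg$read_length))
rr
#> start site overlap ratio: mean 0.063, median 0.074 over 24 fragment lengths
#> verdict: centre_based
```

The centre-anchored distribution peaks exactly at the simulated crosslink
position (−24 nt from the junction, the EJC deposition site) with a 1-nt
FWHM, while the group A start-anchored curve is an order of magnitude
wider (FWHM 12.4 nt here). The mean ratio of 0.063 is far below 1, so the
tool correctly tells you that for this library binding sites should be
assigned from fragment centres, not starts. Rerunning with
`sim_preset("truncation", ...)` flips the diagnosis: mean ratio ≈ 10,
verdict `start_based`.

On real data, start from a coordinate-sorted BAM whose read names carry
the barcode/group annotation written by the preprocessing step
(`id#BC:<umi>#GR:<A|B>`), then `load_fragments()` → `deduplicate()` → the
same calls. A thin command-line wrapper with subcommands `simulate`,
`preprocess`, `dedup`, `junctions`, `distmap`, `overlap` and `basecomp` is
installed at `inst/cli/iclip`.

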