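write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

test_that("the simple SNP dialect round-trips and filters on validation", {
  tf <- write_tsv_lines(character(0))
  expect_equal(nrow(read_snp_table(tf)), 0)

  set.seed(5)
  snps <- snp_records("chr2", sample(1000:2000, 12),
                      sprintf("rs%d", 1:12),
                      major = sample(c("A", "C", "G", "T"), 12, TRUE),
                      minor = NA, validated = rep(c(TRUE, FALSE), 6))
  snps$minor <- ifelse(snps$major == "A", "G", "A")
  tf <- tempfile()
  write_snp_table(snps, tf)
  back <- read_snp_table(tf, validated_only = FALSE)
  expect_equal(back[, c("chrom", "start", "end", "rsid", "major", "minor",
                        "validated")],
               snps[, c("chrom", "start", "end", "rsid", "major", "minor",
                        "validated")])
  expect_equal(nrow(read_snp_table(tf, validated_only = TRUE)), 6)
})

test_that("the supplementary region+SNP dialect is detected and audited", {
  # 5 SNPs in 4 regions: one region holds two SNPs
  lines <- c(
    "chr21\t100\t120\tchr21\t105\t106\trs1",
    "chr21\t100\t120\tchr21\t111\t112\trs2",
    "chr21\t300\t310\tchr21\t305\t306\trs3",
    "chrX\t40\t55\tchrX\t44\t45\trs4",
    "chrX\t70\t90\tchrX\t80\t81\trs5")
  tf <- write_tsv_lines(lines)
  snps <- read_snp_table(tf)
  expect_equal(nrow(snps), 5)
  expect_equal(snps$start[1], 105)
  expect_equal(snps$region_start[1], 100)
  expect_true(all(is.na(snps$major)))
  audit <- audit_snp_table(tf)
  expect_equal(audit$n_records, 5)
  expect_equal(audit$n_regions, 4)
  expect_equal(audit$n_rsids, 5)
})

test_that("malformed SNP tables fail with the line number", {
  tf <- write_tsv_lines(c("chr1\t10\t11\trs1\tA\tG\tTRUE",
                          "chr1\t20\t20\trs2\tA\tG\tTRUE"))
  expect_error(read_snp_table(tf), "line 2")
  tf <- write_tsv_lines("chr1\t10\t11\trs1\tA\tX\tTRUE")
  expect_error(read_snp_table(tf), "allele")
})

test_that("segment/SNP intersection keeps multi-SNP regions as one region", {
  seg <- genomic_intervals("chr1", 10, 20, "seg1")
  seg$length <- 10
  one <- snp_records("chr1", 14, "rs10", "A", "G")
  cand <- intersect_conserved_snps(seg, one)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_snps, 1)

  two <- snp_records("chr1", c(12, 18), c("rsA", "rsB"), "A", "G")
  cand <- intersect_conserved_snps(seg, two)
  expect_equal(nrow(cand), 1)      # one region ...
  expect_equal(cand$n_snps, 2)     # ... two SNPs
  expect_equal(cand$snps[[1]]$rsid, c("rsA", "rsB"))

  # boundary: half-open containment
  edge <- snp_records("chr1", c(9, 10, 19, 20), paste0("rs", 1:4), "A", "G")
  cand <- intersect_conserved_snps(seg, edge)
  expect_equal(cand$snps[[1]]$rsid, c("rs2", "rs3"))
})

test_that("intersection agrees with the all-pairs containment oracle", {
  set.seed(77)
  for (rep in 1:5) {
    segs <- random_intervals(100, chroms = c("chr1", "chr2"))
    segs$name <- sprintf("s%03d", seq_len(nrow(segs)))
    pos <- sample(0:1100, 100, replace = TRUE)
    snps <- snp_records(sample(c("chr1", "chr2"), 100, TRUE), pos,
                        sprintf("rs%03d", 1:100), "A", "G")
    cand <- intersect_conserved_snps(segs, snps)
    want <- oracle_contained_pairs(snps, sort_intervals(segs))
    # same total SNP-in-region pairs and same surviving regions
    expect_equal(sum(cand$n_snps), nrow(want))
    expect_equal(nrow(cand), length(unique(want[, 2])))
    for (i in seq_len(nrow(cand))) {
      s <- cand$snps[[i]]
      expect_true(all(s$start >= cand$start[i] & s$end <= cand$end[i]))
    }
  }
})

test_that("exon masking removes on >= 1 bp overlap, half-open", {
  regions <- intersect_conserved_snps(
    genomic_intervals("chr1", 10, 20),
    snp_records("chr1", 15, "rs1", "A", "G"))
  exon_touch <- data.frame(chrom = "chr1", start = 19, end = 30)
  expect_equal(nrow(exclude_exonic(regions, exon_touch)), 0)
  exon_abut <- data.frame(chrom = "chr1", start = 20, end = 30)
  expect_equal(nrow(exclude_exonic(regions, exon_abut)), 1)
  # post-exclusion disjointness on random inputs
  set.seed(88)
  regs <- random_intervals(120)
  regs$name <- NA; regs$n_snps <- 1L; regs$snps <- list(NULL)
  exons <- random_intervals(40)
  kept <- exclude_exonic(regs, exons)
  want <- regs[!oracle_overlaps_any(regs, exons), , drop = FALSE]
  rownames(want) <- NULL
  expect_equal(kept[, c("chrom", "start", "end")],
               want[, c("chrom", "start", "end")])
  expect_false(any(oracle_overlaps_any(kept, exons)))
})

test_that("exons are read identically from genePred and BED12", {
  # one transcript, chr1:[100,250), exons [100,150) and [200,250)
  gp <- write_tsv_lines(paste(
    "tx1", "chr1", "+", "100", "250", "100", "250", "2",
    "100,200,", "150,250,", sep = "\t"))
  bed12 <- write_tsv_lines(paste(
    "chr1", "100", "250", "tx1", "0", "+", "100", "250", "0", "2",
    "50,50,", "0,100,", sep = "\t"))
  from_gp <- read_exons(gp, format = "genepred")
  from_bed <- read_exons(bed12, format = "bed12")
  expect_equal(from_gp[, c("chrom", "start", "end")],
               from_bed[, c("chrom", "start", "end")])
  expect_equal(from_gp$start, c(100, 200))
  expect_equal(from_gp$end, c(150, 250))
  # auto-detection picks the right reader
  expect_equal(read_exons(gp)$start, c(100, 200))
  expect_equal(read_exons(bed12)$start, c(100, 200))
})

test_that("region extension follows the track / union / fallback rules", {
  core <- genomic_intervals("chr1", 100, 110)
  el <- data.frame(chrom = "chr1", start = 50, end = 900)
  expect_equal(extend_region(core, el)[, c("start", "end")],
               data.frame(start = 50, end = 900))
  # several overlapping elements -> union span
  els <- data.frame(chrom = "chr1", start = c(90, 105), end = c(104, 400))
  expect_equal(extend_region(core, els)$start, 90)
  expect_equal(extend_region(core, els)$end, 400)
  # core equal to an element -> that same interval
  self <- data.frame(chrom = "chr1", start = 100, end = 110)
  expect_equal(extend_region(core, self)[, c("start", "end")],
               data.frame(start = 100, end = 110))
  # no element -> fallback window centered on the core
  far <- genomic_intervals("chr1", 1000, 1010)
  win <- extend_region(far, NULL, fallback_width = 500)
  expect_equal(win$end - win$start, 500)
  expect_equal(win$start, 1005 - 250)
  # clipped at the chromosome start, width preserved
  win0 <- extend_region(core, NULL, fallback_width = 500)
  expect_equal(c(win0$start, win0$end), c(0, 500))
  # clipping respects a short chromosome and always contains the core
  short <- extend_region(core, NULL, fallback_width = 500,
                         chrom_length = 300)
  expect_equal(c(short$start, short$end), c(0, 300))
  expect_error(extend_region(core, NULL, fallback_width = 5),
               "at least the core length")
  # elements on another chromosome are ignored
  other <- data.frame(chrom = "chr2", start = 50, end = 900)
  expect_equal(extend_region(far, other, fallback_width = 500)$start, 755)
})
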