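SP3 <- c("human", "mouse", "chicken")

test_that("trio simulation is byte-reproducible under a fixed seed", {
  isl <- data.frame(start = 100, end = 140)
  a <- simulate_trio(5, 800, divergence = 0.4, islands = isl)
  b <- simulate_trio(5, 800, divergence = 0.4, islands = isl)
  expect_identical(a$genomes, b$genomes)
  expect_identical(emit_maf(a$blocks), emit_maf(b$blocks))
  expect_identical(a$manifest, b$manifest)
  c_ <- simulate_trio(6, 800, divergence = 0.4, islands = isl)
  expect_false(identical(a$genomes, c_$genomes))
})

test_that("zero divergence collapses the trio to one identical chromosome", {
  fx <- simulate_trio(3, 400, divergence = 0)
  expect_identical(unname(fx$genomes[1]), unname(fx$genomes[2]))
  expect_identical(unname(fx$genomes[1]), unname(fx$genomes[3]))
  segs <- call_conserved(fx$blocks, SP3, min_length = 5)
  expect_equal(nrow(segs), 1)
  expect_equal(c(segs$start, segs$end), c(0, 400))
})

test_that("planted islands are recovered exactly at high divergence", {
  isl <- data.frame(start = c(150, 600), end = c(155, 620))  # 5 and 20 bp
  for (seed in c(1, 2, 3)) {
    fx <- simulate_trio(seed, 1000, divergence = 0.5, islands = isl)
    segs <- call_conserved(fx$blocks, SP3, min_length = 5)
    keys <- paste(segs$start, segs$end)
    # recall 100%, exact boundaries (forced flank mismatches)
    expect_true(all(paste(isl$start, isl$end) %in% keys))
    # every reported segment is genuinely identical across the genomes
    for (i in seq_len(nrow(segs))) {
      slices <- vapply(SP3, function(sp) {
        substr(fx$genomes[[sp]], segs$start[i] + 1, segs$end[i])
      }, character(1))
      expect_length(unique(slices), 1)
    }
  }
})

test_that("invalid island layouts are rejected", {
  expect_error(simulate_trio(1, 100, islands = data.frame(start = 10, end = 10)),
               ">= 1 base")
  expect_error(simulate_trio(1, 100,
                             islands = data.frame(start = c(10, 15),
                                                  end = c(20, 30))),
               "non-overlapping")
  expect_error(simulate_trio(1, 100,
                             islands = data.frame(start = c(10, 20),
                                                  end = c(20, 30))),
               "separated")
  expect_error(simulate_trio(1, 100, islands = data.frame(start = 90, end = 110)),
               "within the reference")
})

test_that("the MAF emission is a faithful alignment of the genomes", {
  isl <- data.frame(start = 200, end = 260)
  for (indel in c(0, 0.02)) {
    fx <- simulate_trio(11, 900, divergence = 0.3, islands = isl,
                        indel_rate = indel, n_blocks = 4)
    blocks <- parse_maf(emit_maf(fx$blocks))  # survives serialization
    # per species: concatenated ungapped block texts == genome
    for (sp in SP3) {
      rebuilt <- paste(vapply(blocks, function(b) {
        gsub("-", "", b$rows$text[b$rows$species == sp], fixed = TRUE)
      }, character(1)), collapse = "")
      expect_identical(rebuilt, unname(fx$genomes[[sp]]))
    }
    # islands never straddle block boundaries: each island's segment
    # must be recovered whole
    segs <- call_conserved(blocks, SP3, min_length = 5)
    expect_true(paste(200, 260) %in% paste(segs$start, segs$end))
  }
})

test_that("a planted conserved monomer+SNP+peak flows through the pipeline", {
  isl <- data.frame(start = 100, end = 130)
  trio <- simulate_trio(21, 600, divergence = 0.3, islands = isl,
                        suppress_chance_runs = TRUE)
  fx <- plant_features(
    trio,
    monomers = data.frame(island = 1, offset = 10, start = NA,
                          pattern = "ACAAG", strand = "+", snp_at = 5),
    peaks = data.frame(start = 90, end = 140))
  man <- fx$manifest
  segs <- call_conserved(fx$blocks, SP3, min_length = 5)
  snps <- man$planted_snps
  hits <- scan_monomers(fx$genomes[["human"]], chrom = man$chrom)
  cand <- monomeric_candidates(hits, segs, snps)
  peaks <- data.frame(chrom = man$chrom, start = man$planted_peaks$start,
                      end = man$planted_peaks$end)
  cand <- prioritize_by_chip(cand, peaks, filter = TRUE)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$start, cand$end), c(110, 115))
  expect_equal(cand$snp_start, 114)
  expect_true(cand$chip_supported)
  # and the manifest says exactly the same
  expect_equal(candidate_keys(cand),
               candidate_keys(man$expected$monomeric_candidates))
})

test_that("a planted dimer with a SNP in one monomer yields one candidate", {
  isl <- data.frame(start = 100, end = 140)
  trio <- simulate_trio(22, 600, divergence = 0.3, islands = isl,
                        suppress_chance_runs = TRUE)
  fx <- plant_features(
    trio,
    dimers = data.frame(island = 1, offset = 5, up_pattern = "ACAAT",
                        down_pattern = "ACAAA", spacer = 3,
                        snp_monomer = "upstream", snp_at = 2))
  segs <- call_conserved(fx$blocks, SP3, min_length = 5)
  hits <- scan_monomers(fx$genomes[["human"]], chrom = "chr1")
  cand <- dimeric_candidates(find_dimers(hits), segs,
                             fx$manifest$planted_snps)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$snp_monomer, "upstream")
  expect_equal(cand$spacer, 3)
})

test_that("a planted candidate inside an exon is masked out", {
  isl <- data.frame(start = 100, end = 130)
  trio <- simulate_trio(23, 600, divergence = 0.3, islands = isl,
                        suppress_chance_runs = TRUE)
  fx <- plant_features(
    trio,
    monomers = data.frame(island = 1, offset = 10, start = NA,
                          pattern = "ACAAG", strand = "+", snp_at = 5),
    exons = data.frame(start = 112, end = 200))
  man <- fx$manifest
  segs <- call_conserved(fx$blocks, SP3, min_length = 5)
  regions <- intersect_conserved_snps(segs, man$planted_snps)
  exons <- data.frame(chrom = man$chrom, start = man$planted_exons$start,
                      end = man$planted_exons$end)
  expect_equal(nrow(regions), 1)
  expect_equal(nrow(exclude_exonic(regions, exons)), 0)
  expect_equal(nrow(man$expected$candidate_regions), 0)
  expect_equal(nrow(man$expected$monomeric_candidates), 0)
})

test_that("feature collisions are rejected", {
  trio <- simulate_trio(24, 600, divergence = 0.3,
                        islands = data.frame(start = 100, end = 130))
  expect_error(plant_features(
    trio,
    monomers = data.frame(island = c(1, 1), offset = c(10, 12),
                          start = NA, pattern = "ACAAG", strand = "+",
                          snp_at = NA)),
    "collision")
})

test_that("unconserved decoy monomers never become candidates", {
  trio <- simulate_trio(25, 600, divergence = 0.3,
                        islands = data.frame(start = 100, end = 130),
                        suppress_chance_runs = TRUE)
  fx <- plant_features(
    trio,
    monomers = data.frame(island = c(1, NA), offset = c(10, NA),
                          start = c(NA, 300),
                          pattern = c("ACAAG", "ACAAA"),
                          strand = "+", snp_at = c(5, NA)))
  hits <- scan_monomers(fx$genomes[["human"]], chrom = "chr1")
  # the decoy is seen by the scanner ...
  expect_true(any(hits$start == 300 & hits$strand == "+"))
  # ... but is not identical across species
  expect_false(substr(fx$genomes[["human"]], 301, 305) ==
                 substr(fx$genomes[["mouse"]], 301, 305))
  segs <- call_conserved(fx$blocks, SP3, min_length = 5)
  cand <- monomeric_candidates(hits, segs, fx$manifest$planted_snps)
  expect_true(all(cand$start != 300))
})

test_that("noiseless plates recover the planted folds exactly", {
  sim <- simulate_plate(33, c("A", "B"), c(6, 2), allele_ratio = 0.5,
                        noise_cv = 0)
  act <- fold_changes(sim$measurements)
  get <- function(id, allele) act$fold[act$construct_id == id &
                                         act$allele == allele]
  expect_equal(get("A", "major"), 6)
  expect_equal(get("A", "minor"), 3)
  expect_equal(get("B", "major"), 2)
  expect_equal(get("B", "minor"), 1)
  expect_true(all(act$sd_fold == 0))
  # determinism
  sim2 <- simulate_plate(33, c("A", "B"), c(6, 2), allele_ratio = 0.5,
                         noise_cv = 0)
  expect_identical(sim$measurements, sim2$measurements)
})

test_that("fixture files land on disk in standard formats", {
  fx <- pipeline_fixture(9)
  dir <- file.path(tempdir(), "fixture-files")
  paths <- write_fixture(fx, dir)
  expect_true(all(file.exists(paths)))
  # FASTA genomes read back identical
  g <- Biostrings::readDNAStringSet(paths[["fasta_human"]])
  expect_equal(as.character(g[[1]]), unname(fx$genomes[["human"]]))
  # SNP table round-trips through the reader
  snps <- read_snp_table(paths[["snps"]], validated_only = FALSE)
  expect_equal(nrow(snps), nrow(fx$manifest$planted_snps))
  # MAF parses to the same number of blocks
  expect_length(parse_maf(paths[["maf"]]), length(fx$blocks))
  unlink(dir, recursive = TRUE)
})
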