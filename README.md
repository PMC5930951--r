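# consnp

Conserved-allele regulatory SNP discovery and dual-luciferase reporter
scoring.

## What this is for

Common SNPs that sit inside cis-regulatory elements (rSNPs) can change
gene expression in an allele-specific way, but for cell types with
sparse genomic annotation — the peripheral nerve's Schwann cells being
the motivating case — there is little transcription-factor vocabulary
to predict them with. `consnp` implements the strict-conservation
alternative as a tested pipeline, for genomicists who want to go from a
multi-species alignment plus SNP/exon/peak tracks to a ranked panel of
candidate rSNPs, and then score the wet-lab follow-up:

1. call **multiple-species conserved sequences (MCSs)** — maximal runs
   of alignment columns exactly identical across all species
   (case-insensitive, no gaps, no Ns) and at least `min_length = 5` bp
   — from MAF alignments, in reference BED coordinates;
2. intersect MCSs with frequency-validated biallelic SNPs (multi-SNP
   regions stay one region) and remove regions overlapping exons by
   ≥ 1 bp;
3. scan for **SOX10 consensus sites** — the monomeric 5-mers `ACAAA`,
   `ACACA`, `ACAAT`, `ACAAG` and their reverse complements — and for
   head-to-head **dimers** (opposite-strand pairs, spacer 0–31 bp by
   default); a monomeric candidate is a conserved monomer containing a
   SNP, a dimeric candidate needs both monomers conserved but only one
   with a SNP;
4. prioritize by **SOX10 ChIP-Seq peak** overlap;
5. build allele variants: 30-bp SNP-centered window pairs
   (major/minor), consensus disruption calls, and binding-site
   deletion (ΔSOX) sequences;
6. score **dual-luciferase** plates: per-well firefly/renilla
   normalization, fold-change over the empty vector, the strict
   greater-than-five-fold "strong" call, and major-vs-minor contrasts
   with the more active allele set to 100% and Welch-tested at
   p ≤ 0.05.

A seeded synthetic generator (`simulate_trio`, `plant_features`,
`simulate_plate`, `pipeline_fixture`) produces three-species genomes
with planted identical islands, SNPs, exons, motifs, and peaks — with a
manifest stating the exact expected output of every stage — plus
reporter plates with known fold effects, so the whole pipeline is
testable without any downloads.

## Worked example

```r
library(consnp)

fx  <- pipeline_fixture(seed = 1)         # 6-kb trio, planted truth
man <- fx$manifest
segs <- call_conserved(parse_maf(emit_maf(fx$blocks)),
                       species = man$species, min_length = 5)
head(segs[, c("chrom", "start", "end", "length", "name")], 3)
#>   chrom start  end length      name
#> 1  chr1   300  340     40 mcs_00001
#> 2  chr1   800  840     40 mcs_00002
#> 3  chr1  1500 1530     30 mcs_00003
```

Each row is an exact-identity segment (score/length in bases). Feed the
SNP table, exons, and peaks through the annotation and SOX10 stages:

```r
snps    <- man$planted_snps
exons   <- data.frame(chrom = man$chrom, man$planted_exons)
peaks   <- data.frame(chrom = man$chrom, man$planted_peaks)
regions <- exclude_exonic(intersect_conserved_snps(segs, snps), exons)
# 5 candidate regions holding 5 SNPs

hits <- scan_monomers(fx$genomes[["human"]], chrom = "chr1")
mono <- prioritize_by_chip(
  exclude_exonic(monomeric_candidates(hits, segs, snps), exons), peaks)
mono
#>   chrom start  end strand pattern   rsid chip_supported
#> 1  chr1   310  315      +   ACAAG rs0001           TRUE
#> 2  chr1   817  822      +   ACAAA rs0003          FALSE
#> 3  chr1  4606 4611      -   ACAAT rs0004           TRUE
```

Candidates are conserved SOX10 monomers carrying a SNP; `chip_supported`
marks ≥ 1 bp overlap with a ChIP peak. Dimeric candidates report the
two half-site patterns, the spacer, and which monomer holds the SNP.
Finally, score a simulated reporter plate (24 replicates per group,
true fold 6, minor allele at 45.8% of major):

```r
plate <- simulate_plate(seed = 1, "rSOX-like", true_folds = 6,
                        allele_ratio = 0.458, noise_cv = 0.2)
act <- fold_changes(plate$measurements)
act[, c("construct_id", "allele", "n", "fold", "sd_fold", "strong")]
#>   construct_id allele  n     fold   sd_fold strong
#> 1    rSOX-like  major 24 6.170796 0.9776173   TRUE
#> 2    rSOX-like  minor 24 2.583229 0.4169623  FALSE

compare_alleles(act$rep_folds[act$allele == "major"][[1]],
                act$rep_folds[act$allele == "minor"][[1]])
#>   more_active relative_percent      p_value significant method
#> 1       major         41.86217 5.826545e-17        TRUE  welch
```

The major allele is "strong" (fold > 5, strict); the minor allele runs
at ~42% of the major's activity and the difference is significant at
p ≤ 0.05 (Welch). See `vignettes/conserved-rsnp-discovery.Rmd` for the
model, parameter rationale, and the generator's scope.

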