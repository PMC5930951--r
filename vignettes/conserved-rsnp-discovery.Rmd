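---
title: "Conserved-allele regulatory SNP discovery with consnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved-allele regulatory SNP discovery with consnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Regulatory SNPs (rSNPs) are polymorphisms inside cis-acting regulatory
elements that change transcriptional output in an allele-specific way.
Because the non-coding "vocabulary" is incomplete — especially for
under-profiled cell types such as Schwann cells and motor neurons — one
transcription-factor-agnostic route to candidates is strict sequence
conservation: a base that has remained *exactly* identical across
distant vertebrates (human, mouse, chicken) is likely to be under
constraint, and a common SNP sitting on such a base is a candidate
rSNP.

`consnp` implements that route as a set of composable stages:

1. **Exact-identity conservation calling.** From a multi-species MAF
   alignment, call maximal runs of columns in which every requested
   species carries the same non-gap, non-N base (case-insensitively),
   and keep runs of at least `min_length` bases (default **5**). These
   multiple-species conserved sequences (MCSs) are reported in
   reference coordinates, 0-based half-open.
2. **SNP intersection.** Keep MCSs that contain at least one
   frequency-validated biallelic SNP. A region with several SNPs stays
   one region with all SNPs attached, so the SNP count can exceed the
   region count.
3. **Exon masking.** Remove any candidate whose conserved core overlaps
   an annotated exon by one base or more (UTRs count as exonic; the
   exon set is the transcript blocks of a genePred or BED12 file, not
   the transcript span).
4. **SOX10 consensus scanning.** The monomeric consensus is one of four
   literal 5-mers read 5'→3' — `ACAAA`, `ACACA`, `ACAAT`, `ACAAG` — or
   the reverse complement of any of them (reported as minus-strand
   hits). A *dimeric* site is two monomers on opposite strands in a
   head-to-head arrangement. A monomeric candidate is a monomer fully
   contained in one MCS with a SNP inside the monomer; a dimeric
   candidate requires both monomers conserved but only one monomer to
   contain a SNP.
5. **ChIP prioritization.** Candidates whose site span overlaps a
   SOX10 ChIP-Seq peak by ≥ 1 bp are flagged (or filtered).
6. **Allele construction.** 30-bp windows centered on the SNP for
   binding-site prediction, major/minor substitution, consensus
   disruption/creation calls, and binding-site deletion (ΔSOX)
   constructs.
7. **Reporter scoring.** Dual-luciferase wells are normalized
   firefly/renilla; a region's fold-change is its mean normalized
   signal over the empty-vector mean; activity strictly greater than
   **5-fold** is "strong"; allele contrasts set the more active allele
   to 100% and test per-replicate folds at `p ≤ 0.05`.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_length` | 5 | bases | minimum exact-identity run defining an MCS |
| `spacer_min`, `spacer_max` | 0, 31 | bases | allowed gap between dimer monomers; 31 lets a two-monomer site span up to 41 bp, wide enough for the broadest dimeric elements reported for SoxE factors |
| `orientation` | `divergent` | — | head-to-head geometry: minus-strand monomer upstream, plus-strand downstream (HMG boxes reading outward); `convergent` and `both` are selectable because both conventions appear in the SoxE literature and printed site spans alone do not determine the geometry |
| `fallback_width` | 500 | bases | cloneable-region window when a core overlaps no conservation-track element |
| `width` (allele windows) | 30 | bases | window submitted to TFBS prediction; for even widths the SNP occupies 0-based offset `width/2 - 1` (just left of center) — "centered" is ambiguous by one base and this convention is fixed and documented |
| `strong_threshold` | 5 | fold | strict inequality: 5.01 is strong, 5.00 is not |
| `alpha` | 0.05 | — | allele-difference significance level |
| `n_replicates` | 24 | wells | eight technical replicates across three biological replicates |

## Design choices where the design was open

* **Soft-masked bases and Ns.** Lowercase (repeat-masked) bases compare
  case-insensitively: genome-browser alignments soft-mask repeats and
  nothing in the procedure calls for repeat exclusion. An `N` breaks
  identity — it is an unknown, not a match. Both behaviors live in one
  place (`find_identical_segments`) should a user want to change them.
* **Coordinates.** Everything internal is 0-based half-open (BED
  arithmetic); browser-style 1-based inclusive coordinates are converted
  at I/O boundaries. Abutting intervals therefore do not overlap, which
  makes the "≥ 1 bp" exon rule exactly testable.
* **Block boundaries.** Conserved segments never span MAF block
  boundaries: adjacency of separately aligned blocks is an alignment
  artifact, not evidence of one contiguous identical run.
* **Exon masking level.** Region-level removal (the conserved core, not
  the extended cloning region) is the primary semantics; because the
  masking function accepts any interval table, the same operation
  applies at the SNP or motif-site level when composing the SOX10
  branch.
* **Multi-element extension.** A core overlapping several
  conservation-track elements extends to their union span; the
  single-element and no-element cases are prescribed, the multi-element
  case is this package's choice.
* **Fold-change definition.** The headline fold is the ratio of group
  means (region mean normalized signal over empty-vector mean); the
  per-replicate folds are retained for dispersion and testing. A
  bar-plus-SD presentation is compatible with either convention; this
  one is documented and the per-replicate folds make the alternative
  recoverable.
* **Location test.** Welch's two-sided t-test by default: variances are
  unlikely to be equal across constructs with very different
  activities. Pooled-variance and rank-based (Wilcoxon) tests are
  selectable. Two zero-variance groups with equal means are reported as
  100%, not significant, with no test; zero-variance groups with
  different means are a certain difference (p = 0).
* **No multiple-testing correction by default**, matching per-region
  reporting at p ≤ 0.05 across a screen; a Benjamini–Hochberg option is
  available (`compare_alleles_table(..., adjust = "BH")`).
* **Allele orientation.** SNP alleles are stored on the reference plus
  strand; the allele-mismatch error in `apply_allele`/`extract_window`
  is the guard against stale or strand-flipped records. Indel variants
  are out of scope (single-base biallelic only).

## What the synthetic generator emulates — and what it does not

`simulate_trio` draws a uniform-random reference chromosome and mutates
each non-reference species independently per site (substitutions only
by default; optional small indels), except inside *islands*, which are
copied identically into all species. Two constructions make the planted
truth exact rather than probabilistic:

* the single column flanking each island on either side carries a
  forced cross-species mismatch (only when divergence > 0), so each
  island is a *maximal* identical run and is recovered with exact
  boundaries;
* with `suppress_chance_runs = TRUE` — used by `pipeline_fixture()` —
  every 4th column outside islands is also forced to mismatch, so no
  chance identical run can reach the 5-column minimum and the conserved
  segment set equals the island set for *any* seed.

With suppression off, chance identical columns outside islands occur
with per-column probability p = (1 − q)² at divergence q (identity
requires both non-reference species unmutated; a mutation always
changes the base). The expected number of maximal runs of length ≥ k in
a failure-bounded i.i.d. stretch of length L is then
p^k · (1 + (L − k)(1 − p)), and the test suite checks the simulator
against this closed form by Monte-Carlo.

`plant_features` first rewrites island contents with a motif-free
backbone (identical in all species), then writes consensus text, dimer
geometry, SNPs (with by-frequency flags), exons, and peaks into the
genomes, and records in the manifest the expected output of every
pipeline stage — candidate regions after exon masking, monomeric and
dimeric candidates, and the ChIP-supported subset. A post-planting scan
guarantees the only consensus occurrences inside islands are the
planted ones; a violation is an error, never a silent inexactness. The
SNP-bearing monomer of a planted dimer is itself expected as a
monomeric candidate, mirroring how a monomer-level scan sees a dimer's
half-sites.

The generator **does not** emulate: realistic substitution processes
(no transition/transversion bias, no rate heterogeneity, no
phylogenetic tree — a single per-site divergence rate), repeat
structure, linked SNPs or haplotypes, alignment error, binding-site
energetics (hits are literal matches), or plate-position effects
(luminescence noise is i.i.d. log-normal, which matches positivity and
multiplicative error but not edge effects or shared biological-replicate
structure). Tests passing on these fixtures therefore certify the
*logic* of the pipeline — coordinate arithmetic, gating rules,
statistics — not its behavior on the idiosyncrasies of real alignments
or real plates.

## Numerical notes and degenerate inputs

* A MAF block missing a requested species yields no segments (the block
  count is reported in a message) — genome-wide alignments routinely
  omit a species; a malformed block (ragged rows, bad strand, wrong
  ungapped length) is an error naming the block.
* The fallback extension window is clipped to chromosome bounds
  preserving width where possible and always contains the core.
* Windows that would cross a contig edge are an error, never a silent
  truncation.
* Renilla must be positive in every well; a missing empty-vector group
  is a configuration error, not a NaN.
* All generators are deterministic given their seed, byte-for-byte.

## Problem sizes used by the test suite

The oracle-equivalence suites run the conservation caller against a
per-column brute force on 200 random blocks (≤ 500 columns), the
monomer scanner against a sliding-window oracle on 1,000 random 2-kb
sequences, and the dimer finder and interval intersections against
all-pairs oracles. Reporter null simulations use 1,000 plates of 24
replicates per group; simulator limit checks use 200 seeds of a 2-kb
trio. The end-to-end fixture is a 6-kb chromosome with eight planted
islands. These sizes give the Monte-Carlo checks ~3-sigma resolution
while keeping the whole suite inside a couple of minutes.

## Known limitations

* Exact identity is a deliberately strict conservation criterion; true
  regulatory variants in less-conserved sequence are invisible to it,
  and on real data strict conservation does not necessarily enrich
  strongly for functional elements — the reporter stage exists
  precisely because prediction alone is not evidence.
* The dimer spacer window and head-to-head convention are configurable
  approximations; printed site spans constrain but do not determine
  them, so counts on real genomes should be read as
  convention-dependent.
* PWM/energy scoring of SOX10 sites, other transcription factors, peak
  calling, assembly liftover, primer design, and full dbSNP/VCF schema
  support are out of scope; a thin VCF adapter can be layered on
  `snp_records` if needed.
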