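# Seeded synthetic fixtures with known ground truth: a three-species
# genome trio with planted identical islands, planted SNPs / exons /
# SOX10 motifs / ChIP peaks, MAF emission, and reporter plates with
# planted fold effects.
#
# Two constructions keep the ground truth exact rather than
# probabilistic:
#   * the single column on each side of every planted island carries a
#     forced cross-species mismatch (only when divergence > 0), so each
#     island is a maximal identical run and is recovered exactly;
#   * with `suppress_chance_runs = TRUE` (the pipeline preset), every
#     4th column outside islands also carries a forced mismatch, so no
#     chance identical run can reach 5 columns and the conserved-segment
#     set equals the island set for any seed.

alt_base <- function(b) BASES[match(b, BASES) %% 4 + 1]

rand_other_base <- function(b) {
  shift <- sample(1:3, length(b), replace = TRUE)
  BASES[(match(b, BASES) - 1 + shift) %% 4 + 1]
}

in_ranges <- function(pos, ranges) {
  # pos: 0-based positions; ranges: data.frame(start, end) half-open
  if (is.null(ranges) || nrow(ranges) == 0) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(ranges))) {
    out <- out | (pos >= ranges$start[i] & pos < ranges$end[i])
  }
  out
}

#' Simulate a three-species genome trio with planted identical islands
#'
#' Generates a random reference chromosome and two diverged companion
#' genomes: outside the islands each non-reference species substitutes
#' the reference base independently per site at `divergence`; inside the
#' islands all species are identical. Optional small indels can be
#' enabled. A faithful column-wise MAF alignment of the generated
#' sequences is emitted alongside a manifest of the planted truth.
#'
#' @param seed Integer RNG seed; same seed, same bytes out.
#' @param ref_length Reference chromosome length in bases.
#' @param divergence Per-site substitution probability outside islands,
#'   in `[0, 1]`.
#' @param islands Data frame of island intervals (`start`, `end`,
#'   0-based half-open), non-overlapping and separated by at least one
#'   base; each at least 1 bp.
#' @param species Species labels; the first is the reference.
#' @param chrom Chromosome label.
#' @param indel_rate Per-site probability of a 1-base deletion and,
#'   independently, of a short insertion in a non-reference species
#'   (outside islands only); default 0 keeps the alignment gap-free.
#' @param n_blocks Number of MAF blocks to split the alignment into
#'   (split points avoid islands).
#' @param suppress_chance_runs Force a cross-species mismatch every 4th
#'   column outside islands so no chance identical run of length >= 5
#'   can occur (used by [pipeline_fixture()]).
#' @return A list of class `trio_fixture`: `genomes` (named character
#'   vector), `blocks` (MAF alignment blocks), `manifest`.
#' @export
simulate_trio <- function(seed, ref_length, divergence = 0.3,
                          islands = NULL,
                          species = c("human", "mouse", "chicken"),
                          chrom = "chr1", indel_rate = 0, n_blocks = 1,
                          suppress_chance_runs = FALSE) {
  stopifnot(length(species) >= 2, ref_length >= 1)
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  if (is.null(islands)) {
    islands <- data.frame(start = numeric(0), end = numeric(0))
  }
  islands <- islands[order(islands$start), , drop = FALSE]
  if (nrow(islands) > 0) {
    if (any(islands$end <= islands$start)) stop("islands must be >= 1 base")
    if (any(islands$start < 0 | islands$end > ref_length)) {
      stop("islands must lie within the reference")
    }
    if (nrow(islands) > 1 &&
        any(islands$start[-1] < islands$end[-nrow(islands)] + 1)) {
      stop("islands must be non-overlapping and separated by at least one base")
    }
  }
  set.seed(seed)
  L <- ref_length
  ref <- sample(BASES, L, replace = TRUE)
  pos0 <- seq_len(L) - 1
  island_mask <- in_ranges(pos0, islands)
  m <- matrix(rep(ref, length(species)), nrow = length(species), byrow = TRUE)
  rownames(m) <- species
  for (i in seq_along(species)[-1]) {
    mut <- stats::runif(L) < divergence & !island_mask
    if (any(mut)) m[i, mut] <- rand_other_base(ref[mut])
  }
  # forced flank mismatches make each island a maximal identical run
  flanks <- integer(0)
  if (nrow(islands) > 0 && divergence > 0) {
    flanks <- unique(c(islands$start - 1, islands$end))
    flanks <- flanks[flanks >= 0 & flanks < L]
    m[2, flanks + 1] <- alt_base(ref[flanks + 1])
  }
  forced_cols <- integer(0)
  if (suppress_chance_runs) {
    forced_cols <- setdiff(which(pos0 %% 4 == 0 & !island_mask) - 1, flanks)
    if (length(forced_cols)) {
      m[2, forced_cols + 1] <- alt_base(ref[forced_cols + 1])
    }
  }
  # optional small indels (outside islands): deletions blank a species'
  # character; insertions add gap columns where only one species has bases
  aln <- m
  ref_col_pos <- pos0  # reference position carried by each column (-1 = gap)
  if (indel_rate > 0) {
    for (i in seq_along(species)[-1]) {
      del <- stats::runif(L) < indel_rate / 2 & !island_mask &
        !(pos0 %in% c(flanks, forced_cols))
      aln[i, del] <- "-"
    }
    ins_here <- stats::runif(L) < indel_rate / 2 & !island_mask
    if (any(ins_here)) {
      pieces <- list()
      pieces_pos <- list()
      last <- 0L
      for (p in which(ins_here)) {
        pieces[[length(pieces) + 1L]] <- aln[, (last + 1):p, drop = FALSE]
        pieces_pos[[length(pieces_pos) + 1L]] <- ref_col_pos[(last + 1):p]
        k <- sample(1:2, 1)
        sp <- sample(seq_along(species)[-1], 1)
        col <- matrix("-", nrow = length(species), ncol = k)
        col[sp, ] <- sample(BASES, k, replace = TRUE)
        pieces[[length(pieces) + 1L]] <- col
        pieces_pos[[length(pieces_pos) + 1L]] <- rep(-1, k)
        last <- p
      }
      if (last < L) {
        pieces[[length(pieces) + 1L]] <- aln[, (last + 1):L, drop = FALSE]
        pieces_pos[[length(pieces_pos) + 1L]] <- ref_col_pos[(last + 1):L]
      }
      aln <- do.call(cbind, pieces)
      ref_col_pos <- unlist(pieces_pos)
    }
  }
  genomes <- apply(aln, 1, function(ch) paste(ch[ch != "-"], collapse = ""))
  names(genomes) <- species
  blocks <- trio_blocks(aln, ref_col_pos, species, chrom, islands, n_blocks)
  manifest <- list(seed = seed, chrom = chrom, ref_length = ref_length,
                   divergence = divergence, indel_rate = indel_rate,
                   species = species, islands = islands,
                   forced_flanks = sort(flanks),
                   forced_cols = sort(forced_cols),
                   suppress_chance_runs = suppress_chance_runs,
                   n_blocks = length(blocks))
  structure(list(genomes = genomes, blocks = blocks, manifest = manifest),
            class = "trio_fixture")
}

# Split an alignment matrix into MAF blocks at reference positions
# outside islands (so no island straddles a block boundary).
trio_blocks <- function(aln, ref_col_pos, species, chrom, islands,
                        n_blocks) {
  n_col <- ncol(aln)
  breaks <- 1L
  if (n_blocks > 1) {
    candidates <- which(ref_col_pos >= 0 & !in_ranges(ref_col_pos, islands))
    targets <- round(seq(1, n_col, length.out = n_blocks + 1))[2:n_blocks]
    picks <- vapply(targets, function(t) {
      candidates[which.min(abs(candidates - t))]
    }, numeric(1))
    breaks <- unique(c(1L, sort(picks)))
  }
  bounds <- c(breaks, n_col + 1L)
  lapply(seq_len(length(bounds) - 1), function(k) {
    cols <- bounds[k]:(bounds[k + 1] - 1)
    sub <- aln[, cols, drop = FALSE]
    rows <- do.call(rbind, lapply(seq_along(species), function(i) {
      prior <- if (bounds[k] == 1) 0 else
        sum(aln[i, 1:(bounds[k] - 1)] != "-")
      data.frame(species = species[i], chrom = chrom,
                 start = prior, size = sum(sub[i, ] != "-"),
                 strand = "+", src_size = sum(aln[i, ] != "-"),
                 text = paste(sub[i, ], collapse = ""),
                 stringsAsFactors = FALSE)
    }))
    new_alignment_block(rows, k)
  })
}

# ---------------------------------------------------------------------
# Feature planting

MOTIF_FREE_BACKBONE <- "CCGGA"  # no window of its repetition, nor its
                                # junctions with consensus 5-mers, matches
                                # a SOX10 consensus on either strand

all_consensus_literals <- function() {
  c(sox10_patterns(), revcomp(sox10_patterns()))
}

# 0-based starts of consensus occurrences within chars[from..to] (1-based
# bounds), windows fully inside the range. Independent of scan_monomers.
literal_starts <- function(chars, from, to) {
  if (to - from + 1 < 5) return(integer(0))
  s <- from:(to - 4)
  words <- vapply(s, function(i) paste(chars[i:(i + 4)], collapse = ""),
                  character(1))
  s[words %in% all_consensus_literals()] - 1
}

#' Plant SNPs, exons, SOX10 motifs, and ChIP peaks into a trio fixture
#'
#' Writes exact consensus text (and dimer geometry) into all species at
#' island positions so planted sites are conserved by construction, and
#' augments the manifest with the expected output of every pipeline
#' stage. Requires a substitution-only trio (`indel_rate = 0`).
#'
#' Island contents are first rewritten with a motif-free backbone (all
#' species identically) so that the only consensus occurrences inside
#' islands are the planted ones; this is verified after planting and a
#' violation is an error, keeping the manifest exact.
#'
#' @param trio A [simulate_trio()] result with `indel_rate = 0`.
#' @param monomers Data frame of monomer plants: `island` (1-based index
#'   into the trio's islands, or `NA` with an absolute `start` for an
#'   unconserved plant written into the reference only), `offset`
#'   (within the island), `pattern`, `strand`, `snp_at` (1-5 position of
#'   a planted SNP within the motif, or `NA`).
#' @param dimers Data frame of dimer plants: `island`, `offset`,
#'   `up_pattern`, `down_pattern`, `spacer`, `snp_monomer`
#'   (`"upstream"`/`"downstream"`/`NA`), `snp_at`.
#' @param snps Data frame of plain conserved-region SNP plants:
#'   `island`, `offset`, optional `validated` (default `TRUE`).
#' @param exons,peaks Interval data frames (`start`, `end`) of planted
#'   exons and ChIP peaks.
#' @return The updated `trio_fixture`; `$manifest` gains
#'   `planted_monomers`, `planted_dimers`, `planted_snps`,
#'   `planted_exons`, `planted_peaks`, and `expected` (candidate regions
#'   after exon masking, monomeric and dimeric candidates, and the
#'   ChIP-supported subset).
#' @export
plant_features <- function(trio, monomers = NULL, dimers = NULL,
                           snps = NULL, exons = NULL, peaks = NULL) {
  stopifnot(inherits(trio, "trio_fixture"))
  if (trio$manifest$indel_rate > 0) {
    stop("plant_features requires a substitution-only trio (indel_rate = 0)")
  }
  species <- trio$manifest$species
  chrom <- trio$manifest$chrom
  islands <- trio$manifest$islands
  chars <- lapply(trio$genomes, function(s) strsplit(s, "")[[1]])
  write_all <- function(pos0, text) {
    tchars <- strsplit(text, "")[[1]]
    idx <- (pos0 + 1):(pos0 + length(tchars))
    for (sp in species) chars[[sp]][idx] <<- tchars
  }
  # sterilize islands: motif-free, identical across species
  for (i in seq_len(nrow(islands))) {
    len <- islands$end[i] - islands$start[i]
    backbone <- substr(strrep(MOTIF_FREE_BACKBONE, ceiling(len / 5) + 1),
                       1, len)
    write_all(islands$start[i], backbone)
  }

  planted_motifs <- data.frame(start = numeric(0), end = numeric(0))
  claim <- function(start, end) {
    if (any(planted_motifs$start < end & planted_motifs$end > start)) {
      stop(sprintf("feature collision: planted motifs overlap at [%d, %d)",
                   as.integer(start), as.integer(end)))
    }
    planted_motifs <<- rbind(planted_motifs,
                             data.frame(start = start, end = end))
  }
  island_pos <- function(i, offset, len, what) {
    if (i < 1 || i > nrow(islands)) stop("unknown island index ", i)
    p <- islands$start[i] + offset
    if (offset < 0 || p + len > islands$end[i]) {
      stop(sprintf("%s does not fit inside island %d", what, i))
    }
    p
  }
  snp_out <- list()
  rs_n <- 0L
  add_snp <- function(pos0, validated = TRUE) {
    rs_n <<- rs_n + 1L
    major <- chars[[1]][pos0 + 1]
    minor <- choose_minor(chars[[1]], pos0)
    rec <- snp_records(chrom, pos0, sprintf("rs%04d", rs_n),
                       major = major, minor = minor, validated = validated)
    snp_out[[length(snp_out) + 1L]] <<- rec
    rec$rsid
  }

  mono_rows <- list()
  if (!is.null(monomers)) for (k in seq_len(nrow(monomers))) {
    mk <- monomers[k, ]
    conserved <- !is.na(mk$island)
    p <- if (conserved) island_pos(mk$island, mk$offset, 5, "monomer") else
      mk$start
    text <- if (mk$strand == "+") mk$pattern else revcomp(mk$pattern)
    claim(p, p + 5)
    if (conserved) {
      write_all(p, text)
    } else {
      tchars <- strsplit(text, "")[[1]]
      chars[[1]][(p + 1):(p + 5)] <- tchars
      # break cross-species identity deterministically
      chars[[2]][p + 3] <- alt_base(chars[[1]][p + 3])
    }
    rsid <- if (!is.na(mk$snp_at)) add_snp(p + mk$snp_at - 1) else NA_character_
    mono_rows[[k]] <- data.frame(start = p, end = p + 5,
                                 strand = mk$strand, pattern = mk$pattern,
                                 conserved = conserved, rsid = rsid,
                                 stringsAsFactors = FALSE)
  }
  dimer_rows <- list()
  if (!is.null(dimers)) for (k in seq_len(nrow(dimers))) {
    dk <- dimers[k, ]
    span <- 10 + dk$spacer
    p <- island_pos(dk$island, dk$offset, span, "dimer")
    up_start <- p
    down_start <- p + 5 + dk$spacer
    claim(up_start, up_start + 5)
    claim(down_start, down_start + 5)
    write_all(up_start, revcomp(dk$up_pattern))  # upstream monomer on minus
    write_all(down_start, dk$down_pattern)       # downstream on plus
    rsid <- NA_character_
    if (!is.na(dk$snp_monomer)) {
      base0 <- if (dk$snp_monomer == "upstream") up_start else down_start
      rsid <- add_snp(base0 + dk$snp_at - 1)
    }
    dimer_rows[[k]] <- data.frame(start = up_start, end = down_start + 5,
                                  spacer = dk$spacer,
                                  up_pattern = dk$up_pattern,
                                  down_pattern = dk$down_pattern,
                                  snp_monomer = dk$snp_monomer, rsid = rsid,
                                  stringsAsFactors = FALSE)
  }
  if (!is.null(snps)) for (k in seq_len(nrow(snps))) {
    sk <- snps[k, ]
    p <- island_pos(sk$island, sk$offset, 1, "SNP")
    if (any(planted_motifs$start <= p & p < planted_motifs$end)) {
      stop("feature collision: plain SNP inside a planted motif")
    }
    add_snp(p, validated = if ("validated" %in% names(sk))
      isTRUE(sk$validated) else TRUE)
  }

  # guard: inside each island, consensus occurrences must be exactly the
  # planted ones (the backbone and junctions are designed not to create
  # any; this check makes that a hard invariant of the fixture)
  expected_starts <- sort(c(
    unlist(lapply(mono_rows, function(r) if (r$conserved) r$start else NULL)),
    unlist(lapply(dimer_rows, function(r) c(r$start, r$end - 5)))))
  got <- sort(unlist(lapply(seq_len(nrow(islands)), function(i) {
    literal_starts(chars[[1]], islands$start[i] + 1, islands$end[i])
  })))
  if (!identical(as.numeric(got), as.numeric(expected_starts))) {
    stop("feature collision: accidental consensus occurrence inside an island")
  }

  trio$genomes <- vapply(chars, paste, character(1), collapse = "")
  trio$blocks <- trio_blocks(
    do.call(rbind, chars[species]), seq_len(nchar(trio$genomes[[1]])) - 1,
    species, chrom, islands, trio$manifest$n_blocks)

  planted_snps <- if (length(snp_out)) do.call(rbind, snp_out) else
    snp_records(character(0), numeric(0), character(0))
  planted_monomers <- if (length(mono_rows)) do.call(rbind, mono_rows) else
    NULL
  planted_dimers <- if (length(dimer_rows)) do.call(rbind, dimer_rows) else
    NULL
  exons <- if (is.null(exons)) data.frame(start = numeric(0),
                                          end = numeric(0)) else exons
  peaks <- if (is.null(peaks)) data.frame(start = numeric(0),
                                          end = numeric(0)) else peaks

  trio$manifest$planted_monomers <- planted_monomers
  trio$manifest$planted_dimers <- planted_dimers
  trio$manifest$planted_snps <- planted_snps
  trio$manifest$planted_exons <- exons
  trio$manifest$planted_peaks <- peaks
  trio$manifest$expected <- expected_outputs(
    chrom, islands, planted_monomers, planted_dimers, planted_snps,
    exons, peaks)
  trio
}

# Manifest-side prediction of each pipeline stage, derived from the
# planted truth only (never by running the pipeline itself).
expected_outputs <- function(chrom, islands, monomers, dimers, snps,
                             exons, peaks) {
  valid <- snps[snps$validated, , drop = FALSE]
  overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2
  hits_exon <- function(s, e) {
    nrow(exons) > 0 && any(overlaps(s, e, exons$start, exons$end))
  }
  hits_peak <- function(s, e) {
    nrow(peaks) > 0 && any(overlaps(s, e, peaks$start, peaks$end))
  }
  # candidate regions: islands holding >= 1 validated SNP, exon-masked
  holds_snp <- vapply(seq_len(nrow(islands)), function(i) {
    any(valid$start >= islands$start[i] & valid$start < islands$end[i])
  }, logical(1))
  exonic <- vapply(seq_len(nrow(islands)), function(i) {
    hits_exon(islands$start[i], islands$end[i])
  }, logical(1))
  regions <- islands[holds_snp & !exonic, , drop = FALSE]
  regions <- if (nrow(regions)) {
    r <- genomic_intervals(chrom, regions$start, regions$end)
    r$snp_rsids <- lapply(seq_len(nrow(r)), function(i) {
      sort(valid$rsid[valid$start >= r$start[i] & valid$start < r$end[i]])
    })
    r
  } else {
    genomic_intervals(character(0), numeric(0), numeric(0))
  }
  # monomeric candidates: conserved monomers with a validated SNP
  # inside, site not overlapping an exon. The SNP-bearing monomer of a
  # planted dimer qualifies too: it is itself a conserved monomer
  # containing a SNP.
  mono_all <- NULL
  if (!is.null(monomers)) {
    mono_all <- monomers[monomers$conserved, c("start", "end", "strand",
                                               "pattern", "rsid"),
                         drop = FALSE]
  }
  if (!is.null(dimers) && nrow(dimers)) {
    from_dimers <- do.call(rbind, lapply(seq_len(nrow(dimers)), function(i) {
      d <- dimers[i, ]
      rbind(
        data.frame(start = d$start, end = d$start + 5, strand = "-",
                   pattern = d$up_pattern,
                   rsid = if (identical(d$snp_monomer, "upstream")) d$rsid
                          else NA_character_, stringsAsFactors = FALSE),
        data.frame(start = d$end - 5, end = d$end, strand = "+",
                   pattern = d$down_pattern,
                   rsid = if (identical(d$snp_monomer, "downstream")) d$rsid
                          else NA_character_, stringsAsFactors = FALSE))
    }))
    mono_all <- rbind(mono_all, from_dimers)
  }
  mono <- NULL
  if (!is.null(mono_all) && nrow(mono_all)) {
    keep <- !is.na(mono_all$rsid) & mono_all$rsid %in% valid$rsid &
      !vapply(seq_len(nrow(mono_all)), function(i) {
        hits_exon(mono_all$start[i], mono_all$end[i])
      }, logical(1))
    mono <- mono_all[keep, , drop = FALSE]
    if (nrow(mono)) {
      mono <- mono[order(mono$start), , drop = FALSE]
      rownames(mono) <- NULL
      mono$chip_supported <- vapply(seq_len(nrow(mono)), function(i) {
        hits_peak(mono$start[i], mono$end[i])
      }, logical(1))
    }
  }
  dim_ <- NULL
  if (!is.null(dimers)) {
    keep <- !is.na(dimers$rsid) & dimers$rsid %in% valid$rsid &
      !vapply(seq_len(nrow(dimers)), function(i) {
        hits_exon(dimers$start[i], dimers$end[i])
      }, logical(1))
    dim_ <- dimers[keep, , drop = FALSE]
    if (nrow(dim_)) {
      dim_$chip_supported <- vapply(seq_len(nrow(dim_)), function(i) {
        hits_peak(dim_$start[i], dim_$end[i])
      }, logical(1))
    }
  }
  list(candidate_regions = regions,
       monomeric_candidates = mono,
       dimeric_candidates = dim_)
}

# Minor allele that creates no consensus occurrence overlapping the SNP
# (falls back to the cyclic alternative if all three would).
choose_minor <- function(chars, pos0) {
  ref <- chars[pos0 + 1]
  for (cand in BASES[BASES != ref]) {
    tmp <- chars
    tmp[pos0 + 1] <- cand
    from <- max(1, pos0 + 1 - 4)
    to <- min(length(tmp), pos0 + 1 + 4)
    st <- literal_starts(tmp, from, to)
    if (!length(st)) return(cand)
  }
  alt_base(ref)
}

#' Simulate a dual-luciferase reporter plate with planted effects
#'
#' Renilla is drawn log-normally around `renilla_mean`; firefly is the
#' construct's true fold times its well's renilla times independent
#' log-normal noise, so each well's normalized ratio is the true fold
#' times multiplicative noise (exactly the true fold when
#' `noise_cv = 0`). Major and minor allele wells are generated per
#' construct (minor true fold = major fold x `allele_ratio`), plus
#' empty-vector wells.
#'
#' @param seed Integer RNG seed.
#' @param constructs Construct IDs.
#' @param true_folds True major-allele fold-changes (recycled).
#' @param allele_ratio Minor/major activity ratio (recycled; 1 = null).
#' @param noise_cv Coefficient of variation of the log-normal noise
#'   (default 0.2).
#' @param n_replicates Wells per group (default 24: at least eight
#'   technical replicates across three biological replicates).
#' @param cell_line,orientation,empty_id,renilla_mean Plate labels and
#'   scale.
#' @return A list: `measurements` (plate data frame) and `manifest`
#'   (true folds and allele ratios per construct).
#' @export
simulate_plate <- function(seed, constructs, true_folds, allele_ratio = 1,
                           noise_cv = 0.2, n_replicates = 24,
                           cell_line = "S16", orientation = "forward",
                           empty_id = "EMPTY", renilla_mean = 1e5) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  set.seed(seed)
  true_folds <- rep_len(true_folds, length(constructs))
  allele_ratio <- rep_len(allele_ratio, length(constructs))
  rln <- function(n) {
    if (noise_cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + noise_cv^2))
    exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  }
  well_block <- function(id, orient, allele, fold) {
    renilla <- renilla_mean * rln(n_replicates)
    data.frame(construct_id = id, orientation = orient, allele = allele,
               cell_line = cell_line,
               replicate_id = sprintf("r%02d", seq_len(n_replicates)),
               firefly = fold * renilla * rln(n_replicates),
               renilla = renilla, stringsAsFactors = FALSE)
  }
  parts <- list(well_block(empty_id, "none", "empty", 1))
  for (i in seq_along(constructs)) {
    parts[[length(parts) + 1L]] <-
      well_block(constructs[i], orientation, "major", true_folds[i])
    parts[[length(parts) + 1L]] <-
      well_block(constructs[i], orientation, "minor",
                 true_folds[i] * allele_ratio[i])
  }
  measurements <- do.call(rbind, parts)
  rownames(measurements) <- NULL
  list(measurements = measurements,
       manifest = data.frame(construct_id = constructs,
                             true_fold = true_folds,
                             allele_ratio = allele_ratio,
                             stringsAsFactors = FALSE))
}

#' The standard pipeline test fixture
#'
#' A 6-kb three-species chromosome (divergence 0.3, chance identical
#' runs suppressed outside islands) with eight planted islands covering
#' every pipeline branch: a ChIP-supported conserved monomer with a SNP,
#' two conserved head-to-head dimers with a SNP in one monomer (one
#' ChIP-supported), an exon-masked monomer+SNP, a plain conserved-region
#' SNP, a motif without a SNP, a frequency-unvalidated SNP, a
#' minimum-length (5 bp) island with a SNP, and an unconserved decoy
#' motif outside the islands.
#'
#' @param seed Integer RNG seed.
#' @return A planted `trio_fixture` (see [plant_features()]).
#' @export
pipeline_fixture <- function(seed) {
  islands <- data.frame(
    start = c(300, 800, 1500, 2200, 2800, 3400, 4000, 4600),
    end   = c(340, 840, 1530, 2220, 2830, 3420, 4005, 4640))
  trio <- simulate_trio(seed, ref_length = 6000, divergence = 0.3,
                        islands = islands, n_blocks = 3,
                        suppress_chance_runs = TRUE)
  plant_features(
    trio,
    monomers = data.frame(
      island = c(1, 3, 5, NA),
      offset = c(10, 5, 12, NA),
      start = c(NA, NA, NA, 5200),
      pattern = c("ACAAG", "ACAAT", "ACACA", "ACAAA"),
      strand = c("+", "+", "-", "+"),
      snp_at = c(5, 2, NA, NA), stringsAsFactors = FALSE),
    dimers = data.frame(
      island = c(2, 8),
      offset = c(8, 6),
      up_pattern = c("ACAAG", "ACAAT"),
      down_pattern = c("ACAAA", "ACACA"),
      spacer = c(4, 6),
      snp_monomer = c("downstream", "upstream"),
      snp_at = c(3, 4), stringsAsFactors = FALSE),
    snps = data.frame(island = c(4, 6, 7), offset = c(7, 5, 2),
                      validated = c(TRUE, FALSE, TRUE)),
    exons = data.frame(start = 1508, end = 1600),
    peaks = data.frame(start = c(290, 4590), end = c(360, 4650)))
}

#' Write a trio fixture's files to a directory
#'
#' Emits FASTA genomes, the MAF alignment, the SNP table (simple
#' dialect), exon and peak BEDs, and the JSON manifest.
#'
#' @param fixture A (planted) `trio_fixture`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- fixture$manifest
  paths <- c()
  for (sp in man$species) {
    p <- file.path(dir, paste0(sp, ".fa"))
    seqs <- Biostrings::DNAStringSet(fixture$genomes[[sp]])
    names(seqs) <- man$chrom
    Biostrings::writeXStringSet(seqs, p)
    paths[paste0("fasta_", sp)] <- p
  }
  paths["maf"] <- file.path(dir, "alignment.maf")
  emit_maf(fixture$blocks, paths[["maf"]])
  if (!is.null(man$planted_snps)) {
    paths["snps"] <- file.path(dir, "snps.tsv")
    write_snp_table(man$planted_snps, paths[["snps"]])
  }
  bed_out <- function(df, file) {
    p <- file.path(dir, file)
    if (nrow(df)) {
      utils::write.table(
        data.frame(man$chrom, as.integer(df$start), as.integer(df$end)),
        p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    } else {
      file.create(p)
    }
    p
  }
  if (!is.null(man$planted_exons)) {
    paths["exons"] <- bed_out(man$planted_exons, "exons.bed")
  }
  if (!is.null(man$planted_peaks)) {
    paths["peaks"] <- bed_out(man$planted_peaks, "peaks.bed")
  }
  paths["manifest"] <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(paths)
}
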