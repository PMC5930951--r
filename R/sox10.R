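# SOX10 consensus scanning and candidate gating.
#
# The monomeric consensus is one of four literal 5-mers read 5'->3'
# (ACAAA, ACACA, ACAAT, ACAAG); minus-strand occurrences are reverse
# complements of these on the reference. Dimeric sites are two monomers
# on opposite strands (head-to-head); the coordinate geometry of
# "head-to-head" is configurable because both conventions appear in the
# SoxE literature. Default: divergent (minus-strand monomer upstream,
# plus-strand monomer downstream, HMG boxes reading outward).

#' The four SOX10 monomeric consensus 5-mers
#'
#' @return Character vector `c("ACAAA", "ACACA", "ACAAT", "ACAAG")`.
#' @export
sox10_patterns <- function() c("ACAAA", "ACACA", "ACAAT", "ACAAG")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Scan a sequence for SOX10 monomeric consensus sites
#'
#' Reports every occurrence (including overlapping ones) of the four
#' consensus 5-mers on the plus strand and of their reverse complements
#' as minus-strand hits. Matching is case-insensitive; `N` never
#' matches.
#'
#' @param seq A DNA string over A/C/G/T/N (any case).
#' @param chrom Chromosome label for the reported coordinates.
#' @param offset 0-based genomic position of the first base of `seq`.
#' @return A data frame of motif hits: `chrom`, `start`, `end` (0-based
#'   half-open, length 5), `strand`, `pattern` (consensus as read 5'->3'
#'   on the hit strand), `matched` (equal to `pattern`), sorted by
#'   position then strand.
#' @export
scan_monomers <- function(seq, chrom = "seq", offset = 0) {
  seq <- as.character(seq)
  stopifnot(length(seq) == 1)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence contains characters outside A/C/G/T/N")
  }
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      pattern = character(0), matched = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(seq) < 5) return(empty)
  subj <- Biostrings::DNAString(toupper(seq))
  one <- function(pat, strand, literal) {
    m <- Biostrings::matchPattern(literal, subj, fixed = TRUE)
    if (length(m) == 0) return(NULL)
    data.frame(chrom = chrom, start = offset + Biostrings::start(m) - 1,
               end = offset + Biostrings::end(m), strand = strand,
               pattern = pat, matched = pat, stringsAsFactors = FALSE)
  }
  pats <- sox10_patterns()
  hits <- c(lapply(pats, function(p) one(p, "+", p)),
            lapply(pats, function(p) one(p, "-", revcomp(p))))
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(empty)
  hits <- hits[order(hits$start, hits$strand, hits$pattern), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Pair monomer hits into head-to-head dimers
#'
#' Enumerates all ordered pairs of opposite-strand monomer hits whose
#' spacer (bases between the two monomer intervals) lies within the
#' configured range. A monomer may participate in several dimers.
#'
#' @param hits Monomer hits ([scan_monomers()]), one chromosome.
#' @param spacer_min,spacer_max Allowed spacer range in bases
#'   (defaults 0 and 31).
#' @param orientation `"divergent"` (upstream monomer on minus strand —
#'   the default head-to-head geometry), `"convergent"` (upstream on
#'   plus), or `"both"` (any opposite-strand pair).
#' @return A data frame of dimer hits: upstream/downstream monomer
#'   coordinates, strands and patterns, `spacer`, and the covering
#'   `start`/`end` span.
#' @export
find_dimers <- function(hits, spacer_min = 0, spacer_max = 31,
                        orientation = c("divergent", "convergent", "both")) {
  orientation <- match.arg(orientation)
  if (spacer_min > spacer_max) stop("spacer_min must not exceed spacer_max")
  if (spacer_min < 0) stop("spacer_min must be >= 0")
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), spacer = numeric(0),
                      up_start = numeric(0), up_end = numeric(0),
                      up_strand = character(0), up_pattern = character(0),
                      down_start = numeric(0), down_end = numeric(0),
                      down_strand = character(0), down_pattern = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) < 2) return(empty)
  if (length(unique(hits$chrom)) > 1) {
    parts <- lapply(split(hits, hits$chrom), find_dimers,
                    spacer_min = spacer_min, spacer_max = spacer_max,
                    orientation = orientation)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    return(out)
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  n <- nrow(hits)
  up <- rep(seq_len(n), each = n)
  dn <- rep(seq_len(n), times = n)
  spacer <- hits$start[dn] - hits$end[up]
  keep <- spacer >= spacer_min & spacer <= spacer_max &
    hits$strand[up] != hits$strand[dn]
  keep <- keep & switch(orientation,
    divergent = hits$strand[up] == "-",
    convergent = hits$strand[up] == "+",
    both = TRUE)
  if (!any(keep)) return(empty)
  up <- up[keep]; dn <- dn[keep]
  out <- data.frame(chrom = hits$chrom[up],
                    start = hits$start[up], end = hits$end[dn],
                    spacer = hits$start[dn] - hits$end[up],
                    up_start = hits$start[up], up_end = hits$end[up],
                    up_strand = hits$strand[up], up_pattern = hits$pattern[up],
                    down_start = hits$start[dn], down_end = hits$end[dn],
                    down_strand = hits$strand[dn], down_pattern = hits$pattern[dn],
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(kind = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), strand = character(0), pattern = character(0),
             spacer = numeric(0), rsid = character(0), snp_start = numeric(0),
             snp_monomer = character(0), chip_supported = logical(0),
             stringsAsFactors = FALSE)
}

#' Monomeric SOX10 candidates: conserved sites containing a SNP
#'
#' A monomer hit qualifies when all five of its bases lie inside one
#' conserved segment and at least one SNP lies inside the monomer
#' interval; one candidate is emitted per (hit, SNP) pair. Exon masking
#' is a separate, caller-applied step ([exclude_exonic()]).
#'
#' @param hits Monomer hits ([scan_monomers()]).
#' @param segments Conserved segments ([call_conserved()]).
#' @param snps SNP records.
#' @return A candidate data frame (`kind = "monomer"`): site interval,
#'   strand, pattern, the contained SNP, and a `chip_supported` flag
#'   initialized to `FALSE`.
#' @export
monomeric_candidates <- function(hits, segments, snps) {
  if (nrow(hits) == 0 || nrow(segments) == 0 || nrow(snps) == 0) {
    return(empty_candidates())
  }
  conserved <- unique(within_hits(hits, segments)$query)
  h <- within_hits(snps, hits)
  h <- h[h$subject %in% conserved, , drop = FALSE]
  if (nrow(h) == 0) return(empty_candidates())
  out <- data.frame(kind = "monomer",
                    chrom = hits$chrom[h$subject],
                    start = hits$start[h$subject], end = hits$end[h$subject],
                    strand = hits$strand[h$subject],
                    pattern = hits$pattern[h$subject],
                    spacer = NA_real_,
                    rsid = snps$rsid[h$query], snp_start = snps$start[h$query],
                    snp_monomer = NA_character_, chip_supported = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dimeric SOX10 candidates
#'
#' A dimer qualifies when both monomers are conserved (each fully inside
#' a conserved segment) but only one monomer is required to contain a
#' SNP. One candidate is emitted per (dimer, SNP) pair, annotated with
#' which monomer carries the SNP.
#'
#' @param dimers Dimer hits ([find_dimers()]).
#' @param segments Conserved segments.
#' @param snps SNP records.
#' @return A candidate data frame (`kind = "dimer"`) whose interval is
#'   the dimer span.
#' @export
dimeric_candidates <- function(dimers, segments, snps) {
  if (nrow(dimers) == 0 || nrow(segments) == 0 || nrow(snps) == 0) {
    return(empty_candidates())
  }
  up <- data.frame(chrom = dimers$chrom, start = dimers$up_start,
                   end = dimers$up_end, stringsAsFactors = FALSE)
  dn <- data.frame(chrom = dimers$chrom, start = dimers$down_start,
                   end = dimers$down_end, stringsAsFactors = FALSE)
  both_cons <- seq_len(nrow(dimers)) %in% within_hits(up, segments)$query &
    seq_len(nrow(dimers)) %in% within_hits(dn, segments)$query
  hu <- within_hits(snps, up)
  hd <- within_hits(snps, dn)
  pairs <- rbind(
    if (nrow(hu)) cbind(hu, monomer = "upstream") else NULL,
    if (nrow(hd)) cbind(hd, monomer = "downstream") else NULL)
  if (is.null(pairs) || nrow(pairs) == 0) return(empty_candidates())
  pairs <- pairs[both_cons[pairs$subject], , drop = FALSE]
  if (nrow(pairs) == 0) return(empty_candidates())
  d <- dimers[pairs$subject, , drop = FALSE]
  out <- data.frame(kind = "dimer", chrom = d$chrom,
                    start = d$start, end = d$end, strand = NA_character_,
                    pattern = paste(d$up_pattern, d$down_pattern, sep = "/"),
                    spacer = d$spacer,
                    rsid = snps$rsid[pairs$query],
                    snp_start = snps$start[pairs$query],
                    snp_monomer = as.character(pairs$monomer),
                    chip_supported = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prioritize candidates by ChIP-Seq peak overlap
#'
#' Flags candidates whose site span overlaps any peak by at least one
#' base. With `filter = TRUE` only the supported candidates are
#' returned.
#'
#' @param candidates Candidates from [monomeric_candidates()] or
#'   [dimeric_candidates()].
#' @param peaks Peak interval table ([read_peaks()] or any `chrom`,
#'   `start`, `end` data frame).
#' @param filter Return only ChIP-supported candidates.
#' @return The candidates with `chip_supported` updated.
#' @export
prioritize_by_chip <- function(candidates, peaks, filter = FALSE) {
  if (nrow(candidates) > 0) {
    candidates$chip_supported <- overlaps_any(candidates, peaks)
  }
  if (filter) {
    candidates <- candidates[candidates$chip_supported, , drop = FALSE]
    rownames(candidates) <- NULL
  }
  candidates
}

#' Read ChIP-Seq peaks from BED or narrowPeak
#'
#' @param path Peak file; narrowPeak is detected by a 10-column layout.
#' @return A sorted interval data frame (`chrom`, `start`, `end`,
#'   `name`).
#' @export
read_peaks <- function(path) {
  ncols <- length(strsplit(readLines(path, n = 1), "\t")[[1]])
  gr <- if (ncols == 10) {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric",
                                      pValue = "numeric", qValue = "numeric",
                                      peak = "integer"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
  nm <- S4Vectors::mcols(gr)$name
  sort_intervals(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = if (is.null(nm)) NA_character_ else nm,
    stringsAsFactors = FALSE))
}
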