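# Allele sequence construction: major/minor substitutions, SNP-centered
# windows for binding-site prediction, consensus disruption calls, and
# binding-site deletions (delta-SOX constructs).

#' Substitute a SNP allele into a sequence
#'
#' Replaces exactly the SNP's base in `seq` (whose genomic frame is
#' `frame`) with `allele`, preserving case elsewhere. The base currently
#' at the SNP offset must equal one of the SNP's two alleles; a mismatch
#' signals wrong coordinates, wrong strand, or a stale SNP record.
#'
#' @param seq DNA string covering `frame`.
#' @param frame One-row interval (`chrom`, `start`, `end`) that `seq`
#'   covers.
#' @param snp A single SNP record (one-row data frame).
#' @param allele Base to substitute (A/C/G/T).
#' @return The modified sequence.
#' @export
apply_allele <- function(seq, frame, snp, allele) {
  frame <- one_interval(frame, "frame")
  allele <- toupper(allele)
  if (!allele %in% BASES) stop("allele must be a single A/C/G/T base")
  if (nchar(seq) != frame$end - frame$start) {
    stop("sequence length does not match the frame")
  }
  if (snp$start < frame$start || snp$start >= frame$end) {
    stop("SNP position lies outside the frame")
  }
  off <- snp$start - frame$start + 1
  cur <- toupper(substr(seq, off, off))
  if (!cur %in% c(snp$major, snp$minor)) {
    stop(sprintf(
      "allele mismatch at %s:%d: sequence has '%s' but SNP %s is %s/%s (check coordinates, strand, or SNP record)",
      snp$chrom, as.integer(snp$start), cur, snp$rsid, snp$major, snp$minor))
  }
  substr(seq, off, off) <- allele
  seq
}

#' Extract a SNP-centered allele window pair
#'
#' Cuts a window of `width` bases centered on the SNP from the genome and
#' returns both allele versions. For even widths the SNP occupies 0-based
#' offset `width/2 - 1` (SNP just left of center — the fixed convention
#' of this package); for odd widths it sits exactly at the center.
#'
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param snp A single SNP record with known major/minor alleles.
#' @param width Window width in bases (default 30).
#' @return An object of class `allele_pair`: list with `snp`, `frame`,
#'   `snp_offset` (1-based within the window), `major_seq`, `minor_seq`.
#' @export
extract_window <- function(genome, snp, width = 30) {
  if (width < 1) stop("width must be >= 1")
  if (!snp$chrom %in% names(genome)) {
    stop(sprintf("chromosome '%s' not present in the genome", snp$chrom))
  }
  chrom_seq <- as.character(genome[[snp$chrom]])
  off0 <- ceiling(width / 2) - 1  # 0-based SNP offset in the window
  fstart <- snp$start - off0
  fend <- fstart + width
  if (fstart < 0 || fend > nchar(chrom_seq)) {
    stop(sprintf(
      "window [%d, %d) for %s crosses the %s boundary (length %d)",
      as.integer(fstart), as.integer(fend), snp$rsid, snp$chrom,
      nchar(chrom_seq)))
  }
  frame <- genomic_intervals(snp$chrom, fstart, fend)
  raw <- substr(chrom_seq, fstart + 1, fend)
  structure(list(
    snp = snp,
    frame = frame,
    snp_offset = off0 + 1,
    major_seq = apply_allele(raw, frame, snp, snp$major),
    minor_seq = apply_allele(raw, frame, snp, snp$minor)
  ), class = "allele_pair")
}

#' @export
print.allele_pair <- function(x, ...) {
  cat(sprintf("Allele pair for %s (%s:%d %s>%s), %d-bp window\n",
              x$snp$rsid, x$snp$chrom, as.integer(x$snp$start),
              x$snp$major, x$snp$minor, nchar(x$major_seq)))
  cat(" major:", x$major_seq, "\n minor:", x$minor_seq, "\n")
  invisible(x)
}

#' Classify the effect of a SNP on SOX10 consensus sites
#'
#' Scans both allele sequences of a window pair and compares the hit
#' sets restricted to hits overlapping the SNP position: `disrupts`
#' (major-only), `creates` (minor-only), `retains` (both), `none`
#' (neither).
#'
#' @param pair An [extract_window()] result.
#' @return A list with `category` and `affected_patterns` (per-allele
#'   character vectors of SNP-overlapping consensus patterns).
#' @export
classify_consensus_effect <- function(pair) {
  stopifnot(inherits(pair, "allele_pair"))
  pos <- pair$snp$start
  snp_hits <- function(seq) {
    h <- scan_monomers(seq, chrom = pair$snp$chrom,
                       offset = pair$frame$start)
    h[h$start <= pos & pos < h$end, , drop = FALSE]
  }
  a <- snp_hits(pair$major_seq)
  b <- snp_hits(pair$minor_seq)
  key <- function(h) paste(h$start, h$strand, h$pattern)
  category <- if (nrow(a) > 0 && nrow(b) > 0) "retains"
  else if (nrow(a) > 0) "disrupts"
  else if (nrow(b) > 0) "creates"
  else "none"
  list(category = category,
       affected_patterns = list(major = unique(a$pattern),
                                minor = unique(b$pattern)),
       major_keys = key(a), minor_keys = key(b))
}

#' Delete a binding site from a sequence
#'
#' Removes the site's bases from `seq` (the in-silico counterpart of a
#' delta-SOX construct); the flanks are joined and the sequence shrinks
#' by the site length. An empty site (`start == end`) leaves the
#' sequence unchanged.
#'
#' @param seq DNA string covering `frame`.
#' @param site Interval to delete, expressed in genomic coordinates and
#'   contained in `frame`.
#' @param frame One-row interval that `seq` covers.
#' @return The shortened sequence.
#' @export
delete_binding_site <- function(seq, site, frame) {
  frame <- one_interval(frame, "frame")
  if (nchar(seq) != frame$end - frame$start) {
    stop("sequence length does not match the frame")
  }
  if (site$start == site$end) return(seq)
  if (site$start < frame$start || site$end > frame$end ||
      site$end < site$start) {
    stop("site to delete lies outside the frame")
  }
  a <- site$start - frame$start       # bases kept on the left
  b <- site$end - frame$start + 1     # first 1-based offset kept on the right
  paste0(substr(seq, 1, a), substr(seq, b, nchar(seq)))
}
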