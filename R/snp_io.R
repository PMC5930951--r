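# SNP table reading/writing.
#
# Two 7-column TSV dialects are supported, auto-detected by content:
#
#   supplementary: region_chrom region_start region_end snp_chrom
#                  snp_start snp_end rsid
#     (the layout of the published region/SNP lists: a BED triplet for
#      the conserved region, a BED triplet for the SNP, then the rs ID)
#
#   simple:        chrom start end rsid major minor validated
#
# Both carry 0-based half-open BED coordinates.

BASES <- c("A", "C", "G", "T")

#' Construct SNP records
#'
#' @param chrom,start Chromosome and 0-based position of each SNP
#'   (simple biallelic SNPs occupy a single base; `end = start + 1`).
#' @param rsid SNP identifiers.
#' @param major,minor Major and minor alleles (plus strand of the
#'   reference); must differ and be in A/C/G/T when supplied.
#' @param maf Optional minor allele frequencies in (0, 0.5].
#' @param validated Logical by-frequency validation flags.
#' @return A data frame of SNP records.
#' @export
snp_records <- function(chrom, start, rsid,
                        major = NA_character_, minor = NA_character_,
                        maf = NA_real_, validated = TRUE) {
  n <- length(start)
  major <- toupper(rep_len(as.character(major), n))
  minor <- toupper(rep_len(as.character(minor), n))
  known <- !is.na(major) & !is.na(minor)
  if (any(known & (!(major %in% BASES) | !(minor %in% BASES)))) {
    stop("SNP alleles must be one of A, C, G, T")
  }
  if (any(known & major == minor)) {
    stop("major and minor alleles must differ")
  }
  maf <- rep_len(as.numeric(maf), n)
  if (any(!is.na(maf) & (maf <= 0 | maf > 0.5))) {
    stop("minor allele frequency must lie in (0, 0.5]")
  }
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(start) + 1, rsid = as.character(rsid),
             major = major, minor = minor, maf = maf,
             validated = rep_len(as.logical(validated), n),
             stringsAsFactors = FALSE)
}

#' Read a 7-column SNP table
#'
#' Auto-detects the dialect: when columns 5 and 6 are both integer the
#' table is the region+SNP supplementary layout, otherwise the simple
#' `chrom start end rsid major minor validated` layout.
#'
#' @param path TSV path (no header).
#' @param validated_only Drop records whose by-frequency flag is FALSE
#'   (only meaningful for the simple dialect, which carries the flag).
#' @return A data frame of SNP records. For the supplementary dialect the
#'   enclosing conserved-region triplet is kept as `region_chrom`,
#'   `region_start`, `region_end` columns and alleles are `NA`.
#' @export
read_snp_table <- function(path, validated_only = TRUE) {
  if (length(readLines(path, n = 1, warn = FALSE)) == 0) {
    return(snp_records(character(0), numeric(0), character(0)))
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", blank.lines.skip = TRUE)
  if (ncol(raw) != 7) {
    stop(sprintf("SNP table must have 7 columns, found %d", ncol(raw)))
  }
  int_like <- function(v) all(grepl("^[0-9]+$", v))
  supplementary <- int_like(raw$V5) && int_like(raw$V6)
  check_coords <- function(start, end, label) {
    s <- suppressWarnings(as.numeric(start))
    e <- suppressWarnings(as.numeric(end))
    if (anyNA(s) || anyNA(e)) {
      stop(sprintf("line %d: non-numeric %s coordinates",
                   which(is.na(s) | is.na(e))[1], label))
    }
    bad <- which(e <= s)
    if (length(bad)) {
      stop(sprintf("line %d: %s end (%d) <= start (%d)",
                   bad[1], label, as.integer(e[bad[1]]), as.integer(s[bad[1]])))
    }
    list(start = s, end = e)
  }
  if (supplementary) {
    rc <- check_coords(raw$V2, raw$V3, "region")
    sc <- check_coords(raw$V5, raw$V6, "SNP")
    out <- data.frame(chrom = raw$V4, start = sc$start, end = sc$end,
                      rsid = raw$V7,
                      major = NA_character_, minor = NA_character_,
                      maf = NA_real_, validated = TRUE,
                      region_chrom = raw$V1, region_start = rc$start,
                      region_end = rc$end, stringsAsFactors = FALSE)
    return(out)
  }
  sc <- check_coords(raw$V2, raw$V3, "SNP")
  alle <- toupper(c(raw$V5, raw$V6))
  if (!all(alle %in% BASES)) {
    bad <- which(!(toupper(raw$V5) %in% BASES) | !(toupper(raw$V6) %in% BASES))[1]
    stop(sprintf("line %d: allele is not one of A, C, G, T", bad))
  }
  flag <- toupper(raw$V7) %in% c("TRUE", "T", "1", "YES", "Y")
  out <- data.frame(chrom = raw$V1, start = sc$start, end = sc$end,
                    rsid = raw$V4, major = toupper(raw$V5),
                    minor = toupper(raw$V6), maf = NA_real_,
                    validated = flag, stringsAsFactors = FALSE)
  if (validated_only) out <- out[out$validated, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write SNP records in the simple 7-column dialect
#'
#' @param snps SNP records ([snp_records()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  df <- data.frame(snps$chrom, as.integer(snps$start), as.integer(snps$end),
                   snps$rsid, snps$major, snps$minor,
                   ifelse(snps$validated, "TRUE", "FALSE"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Audit a SNP table
#'
#' Record-count summary of a SNP table in either dialect: total SNP rows,
#' distinct SNP positions, distinct rs IDs, and (supplementary dialect)
#' distinct enclosing conserved regions. This reproduces the headline
#' bookkeeping of a region/SNP list, where multi-SNP regions make the SNP
#' count exceed the region count.
#'
#' @param path TSV path.
#' @return A list with `n_records`, `n_snps`, `n_rsids`, `n_regions`
#'   (`NA` when the table has no region columns).
#' @export
audit_snp_table <- function(path) {
  snps <- read_snp_table(path, validated_only = FALSE)
  n_regions <- if ("region_chrom" %in% names(snps)) {
    nrow(unique(snps[, c("region_chrom", "region_start", "region_end")]))
  } else {
    NA_integer_
  }
  list(n_records = nrow(snps),
       n_snps = nrow(unique(snps[, c("chrom", "start")])),
       n_rsids = length(unique(snps$rsid)),
       n_regions = n_regions)
}
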