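# Candidate-region assembly: conserved segments x SNPs, exon masking,
# and extension of conserved cores to cloneable regions.

#' Intersect conserved segments with SNPs
#'
#' Builds one candidate region per conserved segment that contains at
#' least one SNP. Regions harboring several SNPs are kept as a single
#' region with all SNPs attached, so the SNP total across the output can
#' exceed the region count.
#'
#' @param segments Conserved segments ([call_conserved()]), or any
#'   interval data frame.
#' @param snps SNP records ([snp_records()] / [read_snp_table()]).
#' @return A data frame of candidate regions: `chrom`, `start`, `end`,
#'   `name`, `n_snps`, and a `snps` list-column holding the contained SNP
#'   records of each region.
#' @export
intersect_conserved_snps <- function(segments, snps) {
  segments <- sort_intervals(segments)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      n_snps = integer(0), stringsAsFactors = FALSE)
  empty$snps <- list()
  if (nrow(segments) == 0 || nrow(snps) == 0) return(empty)
  h <- within_hits(snps, segments)
  if (nrow(h) == 0) return(empty)
  keep <- sort(unique(h$subject))
  out <- segments[keep, c("chrom", "start", "end"), drop = FALSE]
  out$name <- if ("name" %in% names(segments)) segments$name[keep] else
    sprintf("region_%05d", seq_along(keep))
  out$n_snps <- vapply(keep, function(i) sum(h$subject == i), integer(1))
  out$snps <- lapply(keep, function(i) {
    s <- snps[h$query[h$subject == i], , drop = FALSE]
    rownames(s) <- NULL
    s[order(s$start), , drop = FALSE]
  })
  rownames(out) <- NULL
  out
}

#' Remove candidate regions overlapping exons
#'
#' Any region whose conserved core overlaps an exon by one base or more
#' is removed whole; survivors are returned unchanged. Half-open
#' arithmetic: an exon abutting a core does not remove it.
#'
#' @param regions Candidate regions ([intersect_conserved_snps()]).
#' @param exons An exon interval table ([read_exons()] or any data frame
#'   with `chrom`, `start`, `end`).
#' @return The surviving candidate regions.
#' @export
exclude_exonic <- function(regions, exons) {
  if (nrow(regions) == 0) return(regions)
  hit <- overlaps_any(regions, exons)
  out <- regions[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read exon annotations from genePred or BED12
#'
#' Exons are the transcript blocks, not the transcript span; UTR blocks
#' count as exonic. The format is auto-detected (BED12 via
#' \pkg{rtracklayer}; genePred as the tab-separated UCSC table whose
#' exon starts/ends are comma-separated lists).
#'
#' @param path Annotation file path.
#' @param format `"auto"`, `"genepred"`, or `"bed12"`.
#' @return A sorted interval data frame of exons (`chrom`, `start`,
#'   `end`, `name` = transcript ID).
#' @export
read_exons <- function(path, format = c("auto", "genepred", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- strsplit(readLines(path, n = 1), "\t")[[1]]
    # genePred column 4 (txStart) is numeric and column 9/10 hold
    # comma lists; BED12 column 2 is numeric.
    format <- if (length(first) >= 10 && grepl(",", first[9]) &&
                  grepl(",", first[10]) && !grepl("^[0-9]+$", first[1]))
      "genepred" else "bed12"
  }
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "BED")
    blocks <- S4Vectors::mcols(gr)$blocks
    if (is.null(blocks)) {
      ex <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr) - 1,
                       end = GenomicRanges::end(gr),
                       name = names(gr) %||% NA_character_,
                       stringsAsFactors = FALSE)
    } else {
      abs_blocks <- IRanges::shift(blocks, GenomicRanges::start(gr) - 1L)
      n <- S4Vectors::elementNROWS(abs_blocks)
      flat <- unlist(abs_blocks, use.names = FALSE)
      ex <- data.frame(
        chrom = rep(as.character(GenomicRanges::seqnames(gr)), n),
        start = IRanges::start(flat) - 1,
        end = IRanges::end(flat),
        name = rep(S4Vectors::mcols(gr)$name %||% NA_character_, n),
        stringsAsFactors = FALSE)
    }
  } else {
    gp <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "")
    parse_list <- function(v) lapply(strsplit(v, ","), as.numeric)
    starts <- parse_list(gp$V9)
    ends <- parse_list(gp$V10)
    n <- lengths(starts)
    ex <- data.frame(chrom = rep(gp$V2, n),
                     start = unlist(starts),
                     end = unlist(ends),
                     name = rep(gp$V1, n),
                     stringsAsFactors = FALSE)
  }
  sort_intervals(ex)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extend a conserved core to a cloneable region
#'
#' Reproduces the cloning-region rule: if the core overlaps exactly one
#' conservation-track element, the element's interval is returned; if it
#' overlaps several, their union span; if none, a window of
#' `fallback_width` (default ~500 bp) centered on the core, clipped to
#' chromosome bounds while preserving width where possible.
#'
#' @param core A single interval (one-row data frame `chrom`, `start`,
#'   `end`).
#' @param elements Interval table of conservation-track elements (e.g. a
#'   PhastCons BED), possibly empty.
#' @param fallback_width Window width in bases used when no element
#'   overlaps the core; must be at least the core length.
#' @param chrom_length Optional chromosome length for clipping.
#' @return A one-row interval data frame containing the core.
#' @export
extend_region <- function(core, elements = NULL, fallback_width = 500,
                          chrom_length = NULL) {
  core <- one_interval(core, "core")
  if (fallback_width < core$end - core$start) {
    stop("fallback_width must be at least the core length")
  }
  if (!is.null(elements) && nrow(elements) > 0) {
    elements <- elements[elements$chrom == core$chrom, , drop = FALSE]
    hit <- elements[elements$start < core$end & elements$end > core$start, ,
                    drop = FALSE]
    if (nrow(hit) == 1) {
      return(genomic_intervals(core$chrom, hit$start, hit$end))
    }
    if (nrow(hit) > 1) {
      return(genomic_intervals(core$chrom, min(hit$start), max(hit$end)))
    }
  }
  mid <- floor((core$start + core$end) / 2)
  s <- mid - fallback_width %/% 2
  e <- s + fallback_width
  upper <- if (is.null(chrom_length)) Inf else chrom_length
  if (s < 0) { e <- min(e - s, upper); s <- 0 }
  if (e > upper) { s <- max(0, s - (e - upper)); e <- upper }
  # clipping can only shrink on short chromosomes; always keep the core
  s <- min(s, core$start)
  e <- max(e, core$end)
  genomic_intervals(core$chrom, s, e)
}
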