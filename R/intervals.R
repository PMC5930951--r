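# Interval plumbing. All coordinates inside the package are 0-based
# half-open (BED convention); browser-style 1-based inclusive coordinates
# are converted at I/O boundaries only.

#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' (0-based half-open) and an optional `name`. Every interval must be
#' non-empty (`start < end`).
#'
#' @param chrom Chromosome labels.
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions.
#' @param name Optional labels (recycled).
#' @return A data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
#' @examples
#' genomic_intervals("chr1", 10, 20, "core")
genomic_intervals <- function(chrom, start, end, name = NA_character_) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval coordinates must be numeric and non-missing")
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1L]
    stop(sprintf("invalid interval: start %d >= end %d (length must be >= 1)",
                 as.integer(start[bad]), as.integer(end[bad])))
  }
  data.frame(chrom = as.character(chrom), start = start, end = end,
             name = rep_len(as.character(name), length(start)),
             stringsAsFactors = FALSE)
}

# Coerce a 0-based half-open interval table to GRanges (1-based closed).
as_gr <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Indices of rows in `query` overlapping any row of `subject` by >= 1 bp.
# Half-open semantics: abutting intervals do not overlap.
overlaps_any <- function(query, subject) {
  if (is.null(subject) || nrow(subject) == 0 || nrow(query) == 0) {
    return(rep(FALSE, if (is.null(query)) 0 else nrow(query)))
  }
  GenomicRanges::countOverlaps(as_gr(query), as_gr(subject),
                               minoverlap = 1L) > 0
}

# Hits of `query` fully contained within rows of `subject`.
# Returns a data.frame(query, subject) of index pairs.
within_hits <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  h <- GenomicRanges::findOverlaps(as_gr(query), as_gr(subject),
                                   type = "within")
  data.frame(query = S4Vectors::queryHits(h),
             subject = S4Vectors::subjectHits(h))
}

sort_intervals <- function(df) {
  if (nrow(df) <= 1) return(df)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

one_interval <- function(x, what = "interval") {
  if (is.list(x) && !is.data.frame(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.data.frame(x) || nrow(x) != 1) {
    stop(sprintf("%s must be a single interval (one-row data frame)", what))
  }
  if (x$end <= x$start) stop(sprintf("%s has start >= end", what))
  x
}
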