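# Multiple Alignment Format (MAF) parsing and emission.
#
# Each block is a list with elements:
#   rows       data.frame(species, chrom, start, size, strand, src_size, text)
#   n_columns  shared aligned width
#
# MAF "s" line semantics are preserved: `start` is 0-based in the strand's
# own orientation, i.e. for minus-strand rows it is an offset into the
# reverse-complemented source sequence; `src_size` allows conversion back
# to forward coordinates.

ALIGN_ALPHABET <- c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n", "-")

new_alignment_block <- function(rows, index = NA_integer_) {
  widths <- nchar(rows$text)
  if (length(unique(widths)) > 1) {
    stop(sprintf("ragged MAF block %s: rows have unequal column counts (%s)",
                 index, paste(widths, collapse = ", ")))
  }
  if (anyDuplicated(rows$species)) {
    stop(sprintf("MAF block %s has more than one row for species '%s'",
                 index, rows$species[duplicated(rows$species)][1]))
  }
  if (!all(rows$strand %in% c("+", "-"))) {
    stop(sprintf("MAF block %s: unknown strand symbol '%s'",
                 index, setdiff(rows$strand, c("+", "-"))[1]))
  }
  ungapped <- nchar(gsub("-", "", rows$text, fixed = TRUE))
  if (!all(ungapped == rows$size)) {
    bad <- which(ungapped != rows$size)[1]
    stop(sprintf(
      "MAF block %s: row '%s' declares %d bases but its text has %d non-gap characters",
      index, rows$species[bad], rows$size[bad], ungapped[bad]))
  }
  structure(list(rows = rows, n_columns = widths[1]),
            class = "alignment_block")
}

#' Parse a MAF multiple-alignment file
#'
#' Reads Multiple Alignment Format text into a list of alignment blocks.
#' Species labels follow the `species.chrom` convention of the `src`
#' field. Only `a` (block) and `s` (sequence) lines are interpreted;
#' `i`/`e`/`q` annotation lines and comments are skipped.
#'
#' @param x Path to a MAF file, or a character vector of MAF lines.
#' @return A list of alignment blocks, in file order. Each block has
#'   `$rows` (one row per species: `species`, `chrom`, `start`, `size`,
#'   `strand`, `src_size`, `text`) and `$n_columns`. Coordinates keep MAF
#'   semantics: 0-based, with minus-strand starts relative to the
#'   reverse-complemented source.
#' @seealso [emit_maf()] for the inverse operation.
#' @export
parse_maf <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[!grepl("^#", lines)]
  blocks <- list()
  current <- NULL
  idx <- 0L
  flush <- function() {
    if (!is.null(current) && length(current) > 0) {
      rows <- do.call(rbind, current)
      blocks[[length(blocks) + 1L]] <<- new_alignment_block(rows, idx)
    }
    current <<- NULL
  }
  for (ln in lines) {
    if (grepl("^a($|\\s)", ln)) {
      flush()
      idx <- idx + 1L
      current <- list()
    } else if (grepl("^s\\s", ln)) {
      if (is.null(current)) {
        idx <- idx + 1L
        current <- list()
      }
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 7) stop(sprintf("malformed MAF s-line in block %d: '%s'", idx, ln))
      src <- f[2]
      species <- sub("\\..*$", "", src)
      chrom <- if (grepl(".", src, fixed = TRUE)) sub("^[^.]*\\.", "", src) else src
      text <- f[7]
      if (!all(strsplit(text, "")[[1]] %in% ALIGN_ALPHABET)) {
        stop(sprintf("MAF block %d: row '%s' contains characters outside the alignment alphabet",
                     idx, species))
      }
      current[[length(current) + 1L]] <- data.frame(
        species = species, chrom = chrom,
        start = as.numeric(f[3]), size = as.numeric(f[4]),
        strand = f[5], src_size = as.numeric(f[6]), text = text,
        stringsAsFactors = FALSE)
    }
    # blank lines and i/e/q lines fall through
  }
  flush()
  blocks
}

#' Write alignment blocks as MAF text
#'
#' @param blocks A list of alignment blocks as returned by [parse_maf()]
#'   or [simulate_trio()].
#' @param path Optional file path; when `NULL` the MAF text is returned
#'   as a character vector of lines.
#' @return `path` invisibly when writing to a file, otherwise the lines.
#' @export
emit_maf <- function(blocks, path = NULL) {
  out <- c("##maf version=1 scoring=none", "")
  for (b in blocks) {
    out <- c(out, "a score=0.0")
    r <- b$rows
    out <- c(out, sprintf("s %s.%s %d %d %s %d %s",
                          r$species, r$chrom, as.integer(r$start),
                          as.integer(r$size), r$strand,
                          as.integer(r$src_size), r$text))
    out <- c(out, "")
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}
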