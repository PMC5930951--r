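# Exact-identity conservation calling.
#
# A column of an alignment block is "identical" when every requested
# species carries a non-gap, non-N base there and all bases agree
# case-insensitively (soft-masked lowercase counts as its uppercase
# base; N is unknown and never matches). Maximal runs of identical
# columns of at least `min_length` are reported as conserved segments in
# reference coordinates. Segments never span block boundaries: adjacency
# of blocks is an alignment artifact, not evidence of one contiguous
# identical run.

# Forward-strand (0-based half-open) coordinates of an aligned row slice.
row_forward_coords <- function(row, local_start, len) {
  if (row$strand == "+") {
    fstart <- row$start + local_start
  } else {
    fstart <- row$src_size - (row$start + local_start + len)
  }
  c(start = fstart, end = fstart + len)
}

#' Find exactly identical segments within one alignment block
#'
#' Scans the block's columns for maximal runs where all requested species
#' have the same (case-insensitive) non-gap, non-N base, and reports runs
#' of at least `min_length` in reference-species coordinates.
#'
#' @param block An alignment block from [parse_maf()].
#' @param species Character vector of species that must all agree.
#' @param min_length Minimum run length in bases (default 5).
#' @param ref Reference species whose coordinates are reported; must be
#'   one of `species`.
#' @return A data frame of conserved segments: `chrom`, `start`, `end`
#'   (reference, 0-based half-open), `length`, and a `species_coords`
#'   list-column giving each species' own forward-strand coordinates of
#'   the identical slice. Blocks missing a requested species yield zero
#'   rows (attribute `skipped = TRUE`), not an error.
#' @export
find_identical_segments <- function(block, species, min_length = 5,
                                    ref = species[1]) {
  if (!ref %in% species) {
    stop("reference species must be a member of the requested species set")
  }
  if (min_length < 1) stop("min_length must be >= 1")
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0),
                      stringsAsFactors = FALSE)
  empty$species_coords <- list()
  ridx <- match(species, block$rows$species)
  if (anyNA(ridx)) {
    attr(empty, "skipped") <- TRUE
    return(empty)
  }
  rows <- block$rows[ridx, , drop = FALSE]
  m <- do.call(rbind, strsplit(toupper(rows$text), "", fixed = TRUE))
  base <- m[1, ]
  ok <- base != "-" & base != "N"
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) ok <- ok & m[i, ] == base
  }
  r <- rle(ok)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  if (!any(keep)) return(empty)
  starts <- run_start[keep]
  lens <- r$lengths[keep]
  # per-row cumulative non-gap counts map columns to sequence offsets
  nongap <- lapply(seq_len(nrow(m)), function(i) cumsum(m[i, ] != "-"))
  ref_row <- rows[match(ref, rows$species), ]
  ref_cum <- nongap[[match(ref, rows$species)]]
  segs <- lapply(seq_along(starts), function(k) {
    a <- starts[k]; len <- lens[k]
    rc <- row_forward_coords(ref_row, ref_cum[a] - 1, len)
    sp <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      cc <- row_forward_coords(rows[i, ], nongap[[i]][a] - 1, len)
      data.frame(species = rows$species[i], chrom = rows$chrom[i],
                 start = cc["start"], end = cc["end"],
                 strand = rows$strand[i], stringsAsFactors = FALSE,
                 row.names = NULL)
    }))
    list(chrom = ref_row$chrom, start = rc[["start"]], end = rc[["end"]],
         length = len, species_coords = sp)
  })
  out <- data.frame(
    chrom = vapply(segs, `[[`, character(1), "chrom"),
    start = vapply(segs, `[[`, numeric(1), "start"),
    end = vapply(segs, `[[`, numeric(1), "end"),
    length = vapply(segs, `[[`, numeric(1), "length"),
    stringsAsFactors = FALSE)
  out$species_coords <- lapply(segs, `[[`, "species_coords")
  sort_intervals(out)
}

#' Call conserved segments across a set of alignment blocks
#'
#' Applies [find_identical_segments()] to every block and concatenates
#' the calls, sorted by reference coordinate. Abutting segments from
#' distinct blocks are never merged. Blocks that do not contain every
#' requested species are skipped; a message reports how many.
#'
#' @inheritParams find_identical_segments
#' @param blocks List of alignment blocks.
#' @return A data frame of conserved segments (see
#'   [find_identical_segments()]) with an added `name` column of
#'   auto-generated segment IDs.
#' @export
call_conserved <- function(blocks, species, min_length = 5,
                           ref = species[1]) {
  per_block <- lapply(blocks, find_identical_segments,
                      species = species, ref = ref, min_length = min_length)
  n_skipped <- sum(vapply(per_block, function(x) isTRUE(attr(x, "skipped")),
                          logical(1)))
  if (n_skipped > 0) {
    message(sprintf("call_conserved: skipped %d block(s) missing a requested species",
                    n_skipped))
  }
  out <- do.call(rbind, per_block)
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0),
                      stringsAsFactors = FALSE)
    out$species_coords <- list()
    out$name <- character(0)
    return(out)
  }
  out <- sort_intervals(out)
  rownames(out) <- NULL
  out$name <- sprintf("mcs_%05d", seq_len(nrow(out)))
  out
}

#' Write conserved segments as BED6
#'
#' Emits one BED6 record per segment (`score` = segment length,
#' `strand` = `*`) via \pkg{rtracklayer}.
#'
#' @param segments Output of [call_conserved()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  gr <- as_gr(segments)
  if (length(gr) > 0) {
    names(gr) <- segments$name
    S4Vectors::mcols(gr)$score <- segments$length
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
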