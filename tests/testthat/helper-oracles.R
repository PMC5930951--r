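# Brute-force oracles and random-input generators. Oracles are written
# as plain per-element loops, independent of the vectorized /
# Biostrings / GenomicRanges code paths they check.

ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_PATTERNS <- c("ACAAA", "ACACA", "ACAAT", "ACAAG")

oracle_rc <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
ORACLE_RC_PATTERNS <- oracle_rc(ORACLE_PATTERNS)

# --- conservation ----------------------------------------------------

# Per-column identity marking + manual run extraction + manual
# coordinate mapping by walking columns.
oracle_segments <- function(block, species, min_length = 5,
                            ref = species[1]) {
  idx <- match(species, block$rows$species)
  if (anyNA(idx)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0)))
  }
  rows <- block$rows[idx, ]
  chars <- lapply(rows$text, function(t) strsplit(toupper(t), "")[[1]])
  nc <- block$n_columns
  ident <- logical(nc)
  for (j in seq_len(nc)) {
    cs <- vapply(chars, `[`, character(1), j)
    ident[j] <- !any(cs %in% c("-", "N")) && length(unique(cs)) == 1
  }
  ref_i <- match(ref, rows$species)
  ref_row <- rows[ref_i, ]
  # local (strand-space) offset of each column's reference base
  local <- integer(nc)
  seen <- 0L
  for (j in seq_len(nc)) {
    if (chars[[ref_i]][j] != "-") {
      local[j] <- seen
      seen <- seen + 1L
    } else {
      local[j] <- NA_integer_
    }
  }
  out <- list()
  j <- 1L
  while (j <= nc) {
    if (ident[j]) {
      k <- j
      while (k < nc && ident[k + 1L]) k <- k + 1L
      len <- k - j + 1L
      if (len >= min_length) {
        loc <- ref_row$start + local[j]
        fstart <- if (ref_row$strand == "+") loc else
          ref_row$src_size - (loc + len)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ref_row$chrom, start = fstart, end = fstart + len,
          length = len, stringsAsFactors = FALSE)
      }
      j <- k + 1L
    } else {
      j <- j + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start), ]
}

# Random alignment block (gaps, Ns, soft-masked case, random strands),
# materialized through MAF text so the parser is exercised too.
random_block <- function(ncol = 60, species = c("human", "mouse", "chicken"),
                         p_match = 0.55) {
  base <- sample(ORACLE_BASES, ncol, replace = TRUE)
  lines <- c("a score=0")
  for (sp in species) {
    pick <- stats::runif(ncol) < p_match
    chars <- ifelse(pick, base,
                    sample(c(ORACLE_BASES, "-", "N"), ncol, replace = TRUE))
    lower <- stats::runif(ncol) < 0.25
    chars[lower] <- tolower(chars[lower])
    size <- sum(chars != "-")
    start <- sample(0:500, 1)
    src_size <- start + size + sample(0:50, 1)
    strand <- sample(c("+", "-"), 1)
    lines <- c(lines, sprintf("s %s.chr%s %d %d %s %d %s", sp,
                              sample(1:3, 1), start, size, strand, src_size,
                              paste(chars, collapse = "")))
  }
  parse_maf(lines)[[1]]
}

# --- motif scanning --------------------------------------------------

oracle_scan <- function(seq, chrom = "seq", offset = 0) {
  s <- toupper(seq)
  n <- nchar(s)
  out <- data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), strand = character(0),
                    pattern = character(0), matched = character(0),
                    stringsAsFactors = FALSE)
  if (n < 5) return(out)
  words <- substring(s, 1:(n - 4), 5:n)
  rows <- list()
  for (i in seq_along(words)) {
    w <- words[i]
    if (w %in% ORACLE_PATTERNS) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = offset + i - 1, end = offset + i + 4,
        strand = "+", pattern = w, matched = w, stringsAsFactors = FALSE)
    }
    if (w %in% ORACLE_RC_PATTERNS) {
      p <- ORACLE_PATTERNS[match(w, ORACLE_RC_PATTERNS)]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = offset + i - 1, end = offset + i + 4,
        strand = "-", pattern = p, matched = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand, out$pattern), ]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) {
  paste(sample(ORACLE_BASES, n, replace = TRUE), collapse = "")
}

# --- interval logic --------------------------------------------------

oracle_contained_pairs <- function(inner, outer) {
  pairs <- list()
  for (i in seq_len(nrow(inner))) {
    for (j in seq_len(nrow(outer))) {
      if (inner$chrom[i] == outer$chrom[j] &&
          inner$start[i] >= outer$start[j] &&
          inner$end[i] <= outer$end[j]) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(pairs)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, pairs)
}

oracle_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

oracle_dimers <- function(hits, spacer_min, spacer_max, orientation) {
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    for (j in seq_len(nrow(hits))) {
      if (hits$chrom[i] != hits$chrom[j]) next
      spacer <- hits$start[j] - hits$end[i]
      if (spacer < spacer_min || spacer > spacer_max) next
      if (hits$strand[i] == hits$strand[j]) next
      ok <- switch(orientation,
                   divergent = hits$strand[i] == "-",
                   convergent = hits$strand[i] == "+",
                   both = TRUE)
      if (!ok) next
      rows[[length(rows) + 1L]] <- data.frame(
        up_start = hits$start[i], up_strand = hits$strand[i],
        down_start = hits$start[j], down_strand = hits$strand[j],
        spacer = spacer, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(up_start = numeric(0), up_strand = character(0),
                      down_start = numeric(0), down_strand = character(0),
                      spacer = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$up_start, out$down_start), ]
}

random_intervals <- function(n, chroms = "chr1", max_pos = 1000,
                             max_len = 30) {
  start <- sample(0:max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample(1:max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Candidate tables reduced to comparable keys (order-free set equality).
candidate_keys <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(character(0))
  sort(paste(df$start, df$end, df$rsid, df$chip_supported, sep = ":"))
}
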