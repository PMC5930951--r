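# Dual-luciferase reporter scoring.
#
# Firefly luminescence is normalized to the co-transfected renilla
# control well-by-well; region activity is the fold-change of the
# normalized signal over the empty (no-insert) vector; a region is
# called "strong" when its fold-change strictly exceeds the threshold
# (default 5). Allele contrasts express the less active allele relative
# to the more active one (set to 100%) and test the per-replicate folds
# with a two-sample location test (Welch by default).

#' Read reporter plate measurements from CSV
#'
#' One row per well with columns `construct_id`, `orientation`,
#' `allele`, `cell_line`, `replicate_id`, `firefly`, `renilla`.
#'
#' @param path CSV path (with header).
#' @return A measurements data frame.
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("construct_id", "orientation", "allele", "cell_line",
              "replicate_id", "firefly", "renilla")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("plate CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

check_luminescence <- function(measurements) {
  if (any(!is.finite(measurements$renilla) | measurements$renilla <= 0)) {
    stop("renilla luminescence must be positive in every well")
  }
  if (any(!is.finite(measurements$firefly) | measurements$firefly < 0)) {
    stop("firefly luminescence must be non-negative")
  }
  invisible(measurements)
}

#' Fold-changes of reporter constructs over the empty vector
#'
#' Normalizes each well (`firefly / renilla`), then computes, per
#' (construct, orientation, allele, cell line) group, the ratio of the
#' group's mean normalized signal to the empty vector's mean normalized
#' signal in the same cell line. Per-replicate folds (each well's
#' normalized signal over the empty mean) are retained for dispersion
#' and downstream testing. The strong-activity call uses a strict
#' inequality: fold 5.01 is strong at the default threshold, fold 5.00
#' is not.
#'
#' @param measurements Plate measurements ([read_plate()] layout).
#' @param empty_id `construct_id` of the empty (no-insert) vector.
#' @param strong_threshold Fold-change above which a region is "strong"
#'   (default 5, strict).
#' @return A data frame with one row per group: `construct_id`,
#'   `orientation`, `allele`, `cell_line`, `n`, `fold`, `sd_fold`,
#'   `strong`, and a `rep_folds` list-column of per-replicate folds.
#' @export
fold_changes <- function(measurements, empty_id = "EMPTY",
                         strong_threshold = 5) {
  check_luminescence(measurements)
  measurements$ratio <- measurements$firefly / measurements$renilla
  is_empty <- measurements$construct_id == empty_id
  if (!any(is_empty)) {
    stop(sprintf("no wells for empty vector '%s'", empty_id))
  }
  empty_mean <- tapply(measurements$ratio[is_empty],
                       measurements$cell_line[is_empty], mean)
  body <- measurements[!is_empty, , drop = FALSE]
  if (nrow(body) == 0) {
    stop("no non-empty construct wells to score")
  }
  no_ctrl <- setdiff(unique(body$cell_line), names(empty_mean))
  if (length(no_ctrl)) {
    stop("cell line(s) without empty-vector wells: ",
         paste(no_ctrl, collapse = ", "))
  }
  key <- interaction(body$construct_id, body$orientation, body$allele,
                     body$cell_line, drop = TRUE)
  groups <- split(body, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    folds <- g$ratio / empty_mean[[g$cell_line[1]]]
    data.frame(construct_id = g$construct_id[1],
               orientation = g$orientation[1], allele = g$allele[1],
               cell_line = g$cell_line[1], n = nrow(g),
               fold = mean(folds),
               sd_fold = if (nrow(g) >= 2) stats::sd(folds) else NA_real_,
               strong = mean(folds) > strong_threshold,
               stringsAsFactors = FALSE)
  }))
  out$rep_folds <- lapply(groups, function(g) {
    unname(g$ratio / empty_mean[[g$cell_line[1]]])
  })
  out <- out[order(out$construct_id, out$orientation, out$allele,
                   out$cell_line), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare major and minor allele activity
#'
#' The more active allele (larger mean per-replicate fold) is set to
#' 100% and the other expressed relative to it; a two-sided two-sample
#' location test on the per-replicate folds yields the p-value
#' (significant when `p <= alpha`). Two groups with zero variance and
#' equal means are a degenerate case: 100%, not significant, no test.
#'
#' @param major,minor Numeric vectors of per-replicate normalized folds
#'   (each of length >= 2).
#' @param alpha Significance level (default 0.05).
#' @param method `"welch"` (default), `"pooled"` (equal-variance t), or
#'   `"wilcoxon"` (rank-based).
#' @return One-row data frame: `more_active`, `relative_percent`,
#'   `p_value`, `significant`, `method`.
#' @export
compare_alleles <- function(major, minor, alpha = 0.05,
                            method = c("welch", "pooled", "wilcoxon")) {
  method <- match.arg(method)
  if (length(major) < 2 || length(minor) < 2) {
    stop("each allele group needs at least 2 replicates")
  }
  m1 <- mean(major); m2 <- mean(minor)
  degenerate <- stats::sd(major) == 0 && stats::sd(minor) == 0
  if (degenerate && m1 == m2) {
    return(data.frame(more_active = "major", relative_percent = 100,
                      p_value = NA_real_, significant = FALSE,
                      method = "none", stringsAsFactors = FALSE))
  }
  p <- if (degenerate) {
    0  # constant groups with different means: certain difference
  } else if (method == "wilcoxon") {
    stats::wilcox.test(major, minor, exact = FALSE)$p.value
  } else {
    stats::t.test(major, minor, var.equal = method == "pooled")$p.value
  }
  data.frame(
    more_active = if (m1 >= m2) "major" else "minor",
    relative_percent = 100 * min(m1, m2) / max(m1, m2),
    p_value = p,
    significant = p <= alpha,
    method = method, stringsAsFactors = FALSE)
}

#' Allele comparisons across a scored plate
#'
#' Runs [compare_alleles()] for every (construct, orientation, cell
#' line) pair present with both a `major` and a `minor` allele group in
#' a [fold_changes()] table. An optional Benjamini-Hochberg correction
#' across the screen is available (off by default, matching per-region
#' reporting).
#'
#' @param activity A [fold_changes()] result.
#' @param alpha Significance level.
#' @param method Location test, as in [compare_alleles()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data frame with one row per compared pair.
#' @export
compare_alleles_table <- function(activity, alpha = 0.05,
                                  method = "welch", adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  key <- interaction(activity$construct_id, activity$orientation,
                     activity$cell_line, drop = TRUE)
  rows <- lapply(split(activity, key), function(g) {
    maj <- g$rep_folds[g$allele == "major"]
    mnr <- g$rep_folds[g$allele == "minor"]
    if (length(maj) != 1 || length(mnr) != 1) return(NULL)
    cmp <- compare_alleles(maj[[1]], mnr[[1]], alpha = alpha, method = method)
    cbind(data.frame(construct_id = g$construct_id[1],
                     orientation = g$orientation[1],
                     cell_line = g$cell_line[1], stringsAsFactors = FALSE),
          cmp)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) return(NULL)
  if (adjust == "BH") {
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- !is.na(out$p_value) & out$p_value <= alpha
  }
  rownames(out) <- NULL
  out
}
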