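#' Partition two peak sets by minimum-overlap intersection
#'
#' A peak of `a` is *shared* if it overlaps at least one peak of `b` by at
#' least `min_overlap` bp (half-open arithmetic: the overlap of two
#' intervals is `max(0, min(endA, endB) - max(startA, startB))`, so adjacent
#' intervals do not overlap), and *unique* otherwise; symmetrically for
#' `b`. Every qualifying (A, B) pair is enumerated with its overlap length.
#' A peak overlapping several partners still counts once in the shared set.
#'
#' @param a,b [peak_set()] objects.
#' @param min_overlap minimum overlap in bp (>= 1) for two peaks to count
#'   as intersecting.
#' @return An `overlap_result`: peak sets `shared_a`, `unique_a`,
#'   `shared_b`, `unique_b`, a `pairs` data frame
#'   (`name_a`, `name_b`, `overlap`), and the `min_overlap` used.
#' @examples
#' a <- peak_set(data.frame(chrom = "chr1", start = 0, end = 100), "A")
#' b <- peak_set(data.frame(chrom = "chr1", start = 99, end = 200), "B")
#' intersect_peaks(a, b)
#' @export
intersect_peaks <- function(a, b, min_overlap = 1) {
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"))
  if (!is.numeric(min_overlap) || length(min_overlap) != 1 || min_overlap < 1)
    stop("min_overlap must be a single number >= 1")
  lv <- sort(unique(c(a$intervals$chrom, b$intervals$chrom)))
  hits <- GenomicRanges::findOverlaps(ps_granges(a, lv), ps_granges(b, lv),
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$intervals$end[qi], b$intervals$end[si]) -
    pmax(a$intervals$start[qi], b$intervals$start[si])
  keep <- ov >= min_overlap
  qi <- qi[keep]; si <- si[keep]; ov <- ov[keep]
  pairs <- data.frame(name_a = a$intervals$name[qi],
                      name_b = b$intervals$name[si],
                      overlap = ov, stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    o <- order(pairs$name_a, pairs$name_b, method = "radix")
    pairs <- pairs[o, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  in_a <- a$intervals$name %in% pairs$name_a
  in_b <- b$intervals$name %in% pairs$name_b
  structure(list(
    shared_a = subset_peaks(a, in_a, label = paste0(a$label, "_shared")),
    unique_a = subset_peaks(a, !in_a, label = paste0(a$label, "_unique")),
    shared_b = subset_peaks(b, in_b, label = paste0(b$label, "_shared")),
    unique_b = subset_peaks(b, !in_b, label = paste0(b$label, "_unique")),
    pairs = pairs,
    min_overlap = min_overlap,
    label_a = a$label, label_b = b$label
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  na <- n_peaks(x$shared_a) + n_peaks(x$unique_a)
  nb <- n_peaks(x$shared_b) + n_peaks(x$unique_b)
  cat("overlap_result (min overlap ", x$min_overlap, " bp)\n", sep = "")
  cat("  ", x$label_a, ": ", n_peaks(x$shared_a), " shared / ",
      n_peaks(x$unique_a), " unique of ", na, "\n", sep = "")
  cat("  ", x$label_b, ": ", n_peaks(x$shared_b), " shared / ",
      n_peaks(x$unique_b), " unique of ", nb, "\n", sep = "")
  cat("  ", nrow(x$pairs), " overlapping pair(s)\n", sep = "")
  invisible(x)
}

#' Subtelomeric regions of every chromosome
#'
#' The terminal `margin` bp at each end of every chromosome; when
#' `2 * margin` reaches the chromosome length the two margins merge into a
#' single whole-chromosome interval. With `margin = 0` the set is empty.
#'
#' @param chromsizes a [chrom_sizes()] object.
#' @param margin width in bp of each terminal region (default 500 kb).
#' @return A [peak_set()] labelled `"subtelomere"`.
#' @export
subtelomere_regions <- function(chromsizes, margin = 500000) {
  stopifnot(inherits(chromsizes, "chrom_sizes"), margin >= 0)
  rows <- list()
  if (margin > 0) {
    for (chr in names(chromsizes)) {
      L <- unname(chromsizes[chr])
      if (2 * margin >= L) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chr, start = 0, end = L,
          name = paste0("subtel_", chr), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chr, start = c(0, L - margin), end = c(margin, L),
          name = paste0("subtel_", chr, c("_p", "_q")),
          stringsAsFactors = FALSE)
      }
    }
  }
  peak_set(if (length(rows)) do.call(rbind, rows) else NULL,
           label = "subtelomere", chromsizes = chromsizes)
}

#' Remove peaks overlapping any mask region
#'
#' Whole-peak removal: a peak is dropped when it overlaps the union of the
#' masks by one or more bp; peaks are never trimmed. Applying the same
#' masks twice is a no-op.
#'
#' @param peaks a [peak_set()].
#' @param masks a [peak_set()] or list of peak sets (e.g. blacklist plus
#'   subtelomeres).
#' @return The retained peaks, canonically sorted.
#' @export
exclude_regions <- function(peaks, masks) {
  stopifnot(inherits(peaks, "peak_set"))
  if (inherits(masks, "peak_set")) masks <- list(masks)
  mask_df <- do.call(rbind, lapply(masks, function(m) {
    stopifnot(inherits(m, "peak_set"))
    m$intervals[, c("chrom", "start", "end")]
  }))
  if (is.null(mask_df) || !nrow(mask_df) || !n_peaks(peaks))
    return(sort_peaks(peaks))
  lv <- sort(unique(c(peaks$intervals$chrom, mask_df$chrom)))
  gm <- GenomicRanges::GRanges(factor(mask_df$chrom, levels = lv),
                               IRanges::IRanges(mask_df$start + 1,
                                                mask_df$end))
  hit <- GenomicRanges::countOverlaps(ps_granges(peaks, lv), gm,
                                      ignore.strand = TRUE) > 0
  subset_peaks(peaks, !hit)
}

#' Per-chromosome shared/unique peak counts
#'
#' Tabulates an [intersect_peaks()] result by chromosome, separately for
#' the shared and unique partitions of both sets (the per-chromosome view
#' behind a stacked bar chart of peak counts).
#'
#' @param result an `overlap_result`.
#' @return Data frame with columns `chrom`, `shared_a`, `unique_a`,
#'   `shared_b`, `unique_b`; one row per chromosome carrying any peak.
#' @export
per_chromosome_counts <- function(result) {
  stopifnot(inherits(result, "overlap_result"))
  sets <- list(shared_a = result$shared_a, unique_a = result$unique_a,
               shared_b = result$shared_b, unique_b = result$unique_b)
  chroms <- sort(unique(unlist(lapply(sets, function(s) s$intervals$chrom))))
  out <- data.frame(chrom = chroms, stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    tab <- table(factor(sets[[nm]]$intervals$chrom, levels = chroms))
    out[[nm]] <- as.integer(tab)
  }
  rownames(out) <- NULL
  out
}

#' Length summary of shared peaks, per chromosome and source set
#'
#' Peak lengths are `end - start`. Rows appear only for chromosomes with at
#' least one shared peak of the given source.
#'
#' @param result an `overlap_result`.
#' @return Data frame with columns `chrom`, `set`, `n`, `mean`, `median`,
#'   `q1`, `q3`.
#' @export
length_summary <- function(result) {
  stopifnot(inherits(result, "overlap_result"))
  one <- function(ps, label) {
    df <- ps$intervals
    if (!nrow(df)) return(NULL)
    len <- df$end - df$start
    do.call(rbind, lapply(split(len, df$chrom), function(v) {
      q <- unname(quantile(v, c(0.25, 0.75)))
      data.frame(n = length(v), mean = mean(v), median = median(v),
                 q1 = q[1], q3 = q[2])
    })) -> s
    data.frame(chrom = rownames(s), set = label, s,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- rbind(one(result$shared_a, result$label_a),
               one(result$shared_b, result$label_b))
  if (is.null(out))
    out <- data.frame(chrom = character(0), set = character(0),
                      n = integer(0), mean = numeric(0), median = numeric(0),
                      q1 = numeric(0), q3 = numeric(0))
  out[order(out$chrom, out$set, method = "radix"), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
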