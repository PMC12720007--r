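#' Peak sets
#'
#' A `peak_set` is a labelled, ordered collection of genomic intervals in
#' 0-based half-open coordinates, optionally validated against a
#' [chrom_sizes()] object. The interval table always carries the columns
#' `chrom`, `start`, `end`, `name`, `score`, `strand`; any extra columns
#' (e.g. narrowPeak `signal_value`, `p_value`, `q_value`, `summit`) are
#' retained as metadata.
#'
#' @param intervals data frame with at least `chrom`, `start`, `end`.
#'   Missing `name` entries receive generated names; `score` defaults to
#'   `NA`; `strand` defaults to `"."`.
#' @param label single string naming the set (e.g. `"TERRA"`).
#' @param chromsizes optional [chrom_sizes()]; when supplied, every interval
#'   must lie on a known chromosome and within its length.
#' @param sort if `TRUE` (default) intervals are put in canonical
#'   (chrom, start, end, name) order; `FALSE` preserves input order.
#' @return A `peak_set` object.
#' @examples
#' peak_set(data.frame(chrom = "chr1", start = 0, end = 100), label = "demo")
#' @export
peak_set <- function(intervals = NULL, label = "peaks", chromsizes = NULL,
                     sort = TRUE) {
  if (is.null(intervals))
    intervals <- data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0))
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(intervals))
  if (length(miss))
    stop("interval table lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(intervals)
  intervals$chrom <- as.character(intervals$chrom)
  intervals$start <- as.numeric(intervals$start)
  intervals$end <- as.numeric(intervals$end)
  if (is.null(intervals$name) || all(is.na(intervals$name)))
    intervals$name <- if (n) paste0("peak_", seq_len(n)) else character(0)
  intervals$name <- as.character(intervals$name)
  if (is.null(intervals$score)) intervals$score <- rep(NA_real_, n)
  if (is.null(intervals$strand)) intervals$strand <- rep(".", n)
  core <- c("chrom", "start", "end", "name", "score", "strand")
  intervals <- intervals[, c(core, setdiff(names(intervals), core)),
                         drop = FALSE]
  ps <- structure(list(label = as.character(label)[1],
                       intervals = intervals,
                       chromsizes = chromsizes),
                  class = "peak_set")
  validate_peak_set(ps)
  if (sort) ps <- sort_peaks(ps)
  ps
}

validate_peak_set <- function(ps) {
  df <- ps$intervals
  if (!nrow(df)) return(invisible(ps))
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)) ||
      any(df$start != floor(df$start)) || any(df$end != floor(df$end)))
    stop("start/end must be non-negative integers")
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) for peak '",
         df$name[bad[1]], "'")
  if (!all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (anyDuplicated(df$name))
    stop("duplicated peak names: ",
         paste(head(unique(df$name[duplicated(df$name)]), 3), collapse = ", "))
  cs <- ps$chromsizes
  if (!is.null(cs)) {
    unknown <- setdiff(unique(df$chrom), names(cs))
    if (length(unknown))
      stop("chromosome(s) absent from chrom sizes: ",
           paste(unknown, collapse = ", "))
    over <- which(df$end > unname(cs[df$chrom]))
    if (length(over))
      stop("peak '", df$name[over[1]], "' extends beyond chromosome ",
           df$chrom[over[1]])
  }
  invisible(ps)
}

#' Canonical (chrom, start, end, name) ordering of a peak set
#'
#' @param ps a [peak_set()].
#' @return The peak set with intervals in canonical order.
#' @export
sort_peaks <- function(ps) {
  df <- ps$intervals
  if (nrow(df) > 1) {
    o <- order(df$chrom, df$start, df$end, df$name, method = "radix")
    ps$intervals <- df[o, , drop = FALSE]
    rownames(ps$intervals) <- NULL
  }
  ps
}

#' Number of peaks in a set
#' @param ps a [peak_set()].
#' @return Integer count.
#' @export
n_peaks <- function(ps) nrow(ps$intervals)

#' Peak lengths (end - start) in bp
#' @param ps a [peak_set()].
#' @return Numeric vector named by peak.
#' @export
peak_lengths <- function(ps) {
  setNames(ps$intervals$end - ps$intervals$start, ps$intervals$name)
}

#' @export
as.data.frame.peak_set <- function(x, ...) x$intervals

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set '", x$label, "': ", n_peaks(x), " interval(s)",
      if (!is.null(x$chromsizes)) paste0(" on ", length(x$chromsizes),
                                         " chromosome(s)"),
      "\n", sep = "")
  if (n_peaks(x)) {
    print(head(x$intervals, 6), row.names = FALSE)
    if (n_peaks(x) > 6) cat("  ... ", n_peaks(x) - 6, " more\n", sep = "")
  }
  invisible(x)
}

# subset a peak_set by logical/integer index, keeping metadata columns
subset_peaks <- function(ps, idx, label = ps$label, sort = TRUE) {
  out <- ps
  out$label <- label
  out$intervals <- ps$intervals[idx, , drop = FALSE]
  rownames(out$intervals) <- NULL
  if (sort) out <- sort_peaks(out)
  out
}

# GRanges view of a peak_set (1-based closed coordinates); `levels` gives a
# shared seqlevel universe so cross-set overlap calls compare cleanly
ps_granges <- function(ps, levels = NULL) {
  df <- ps$intervals
  if (is.null(levels)) levels <- sort(unique(df$chrom))
  GenomicRanges::GRanges(seqnames = factor(df$chrom, levels = levels),
                         ranges = IRanges::IRanges(start = df$start + 1,
                                                   end = df$end))
}
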