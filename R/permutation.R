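# ---- internal: fast overlap statistic on a single linearised axis ----

# concatenate chromosomes onto one integer axis so a whole genome's
# overlaps resolve in a single IRanges call
axis_offsets <- function(chromsizes) {
  L <- unname(chromsizes)
  setNames(cumsum(c(0, L[-length(L)] + 1)), names(chromsizes))
}

to_axis_ranges <- function(chrom, start0, end0, offsets) {
  off <- unname(offsets[chrom])
  IRanges::IRanges(start = start0 + off + 1, end = end0 + off)
}

# count of A peaks with >= 1 qualifying partner ("shared"), or total pair
# count ("pairs")
overlap_stat <- function(ra, rb, min_overlap, statistic) {
  cnt <- IRanges::countOverlaps(ra, rb,
                                minoverlap = as.integer(min_overlap))
  if (statistic == "shared") sum(cnt > 0) else sum(cnt)
}

# vectorised uniform placement preserving chrom and length; start drawn
# uniformly from 0 .. L - len
draw_starts <- function(len, L) {
  floor(runif(length(len)) * (L - len + 1))
}

#' Randomize peak placement, preserving number, size and chromosome
#'
#' Each peak keeps its chromosome and length and receives a new start drawn
#' uniformly from `[0, L - length]`; peaks are placed independently, so
#' randomized peaks may overlap one another. If `mask` is given, draws
#' intersecting the mask are rejected and redrawn up to `max_tries` rounds,
#' after which an infeasible mask is an error (detecting infeasibility
#' rather than biasing placement).
#'
#' @param peaks a [peak_set()].
#' @param chromsizes a [chrom_sizes()] covering every peak's chromosome.
#' @param seed optional integer seed (`set.seed`) for reproducible draws.
#' @param mask optional [peak_set()] of disallowed regions.
#' @param max_tries redraw rounds before declaring the mask infeasible.
#' @return A [peak_set()] with the same peak names, chromosomes and
#'   lengths, in canonical order.
#' @export
randomize_peaks <- function(peaks, chromsizes, seed = NULL, mask = NULL,
                            max_tries = 1000) {
  stopifnot(inherits(peaks, "peak_set"), inherits(chromsizes, "chrom_sizes"))
  if (!is.null(seed)) set.seed(seed)
  df <- peaks$intervals
  unknown <- setdiff(unique(df$chrom), names(chromsizes))
  if (length(unknown))
    stop("chromosome(s) absent from chrom sizes: ",
         paste(unknown, collapse = ", "))
  L <- unname(chromsizes[df$chrom])
  len <- df$end - df$start
  too_long <- which(len > L)
  if (length(too_long))
    stop("peak '", df$name[too_long[1]], "' is longer than its chromosome")
  start <- draw_starts(len, L)
  if (!is.null(mask) && n_peaks(mask)) {
    off <- axis_offsets(chromsizes)
    rm_ <- to_axis_ranges(mask$intervals$chrom, mask$intervals$start,
                          mask$intervals$end, off)
    tries <- 0
    repeat {
      bad <- IRanges::countOverlaps(
        to_axis_ranges(df$chrom, start, start + len, off), rm_) > 0
      if (!any(bad)) break
      tries <- tries + 1
      if (tries > max_tries)
        stop("mask leaves no legal placement for ", sum(bad),
             " peak(s) after ", max_tries, " retries")
      start[bad] <- draw_starts(len[bad], L[bad])
    }
  }
  out <- df
  out$start <- start
  out$end <- start + len
  peak_set(out, label = peaks$label, chromsizes = chromsizes)
}

#' Permutation test of peak-set overlap
#'
#' Tests whether the observed number of shared peaks (peaks of `a` with at
#' least one `min_overlap`-bp partner in `b`) exceeds what uniform random
#' placement would produce. Each permutation re-randomizes the set(s) named
#' by `randomize` across the genome — preserving each set's peak number,
#' sizes and chromosome distribution — and recomputes the same statistic.
#' The empirical p-value is the proportion of permutations whose statistic
#' is at least the observed value; because that proportion can be zero, the
#' `(r + 1) / (n + 1)` estimator is reported alongside.
#'
#' @param a,b non-empty [peak_set()] objects.
#' @param chromsizes a [chrom_sizes()] (the mappable genome; optionally
#'   reduced by `mask`).
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed; fixed seed gives bit-identical null
#'   counts.
#' @param min_overlap intersection threshold in bp (default 1).
#' @param randomize which set(s) to re-place each permutation.
#' @param mask optional [peak_set()] of disallowed placement regions
#'   (e.g. blacklist + subtelomeres).
#' @param statistic `"shared"` counts A peaks with >= 1 partner (the peak
#'   count a shared/unique partition reports); `"pairs"` counts all
#'   qualifying pairs.
#' @param check_conservation re-assert the (chrom, length) multiset
#'   invariant every permutation (test mode; slower).
#' @return A `perm_test` object: `observed`, `null_counts`, `p_empirical`,
#'   `p_pseudocount`, `null_mean`, `null_sd`, `z_score`, and the
#'   configuration used.
#' @export
permutation_test <- function(a, b, chromsizes, n_perm = 1000, seed = NULL,
                             min_overlap = 1,
                             randomize = c("both", "a_only", "b_only"),
                             mask = NULL,
                             statistic = c("shared", "pairs"),
                             check_conservation = FALSE) {
  randomize <- match.arg(randomize)
  statistic <- match.arg(statistic)
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"))
  if (!n_peaks(a) || !n_peaks(b)) stop("both peak sets must be non-empty")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  off <- axis_offsets(chromsizes)
  for (ps in list(a, b)) {
    unknown <- setdiff(unique(ps$intervals$chrom), names(chromsizes))
    if (length(unknown))
      stop("chromosome(s) absent from chrom sizes: ",
           paste(unknown, collapse = ", "))
  }
  da <- a$intervals; db <- b$intervals
  La <- unname(chromsizes[da$chrom]); Lb <- unname(chromsizes[db$chrom])
  lena <- da$end - da$start; lenb <- db$end - db$start
  if (any(lena > La) || any(lenb > Lb))
    stop("a peak is longer than its chromosome")
  mask_r <- if (!is.null(mask) && n_peaks(mask))
    to_axis_ranges(mask$intervals$chrom, mask$intervals$start,
                   mask$intervals$end, off) else NULL
  place <- function(chrom, len, L) {
    s <- draw_starts(len, L)
    if (!is.null(mask_r)) {
      tries <- 0
      repeat {
        bad <- IRanges::countOverlaps(to_axis_ranges(chrom, s, s + len, off),
                                      mask_r) > 0
        if (!any(bad)) break
        tries <- tries + 1
        if (tries > 1000)
          stop("mask leaves no legal placement after 1000 retries")
        s[bad] <- draw_starts(len[bad], L[bad])
      }
    }
    s
  }
  ra_obs <- to_axis_ranges(da$chrom, da$start, da$end, off)
  rb_obs <- to_axis_ranges(db$chrom, db$start, db$end, off)
  observed <- overlap_stat(ra_obs, rb_obs, min_overlap, statistic)
  null_counts <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    ra <- ra_obs; rb <- rb_obs
    if (randomize %in% c("both", "a_only")) {
      sa <- place(da$chrom, lena, La)
      ra <- to_axis_ranges(da$chrom, sa, sa + lena, off)
    }
    if (randomize %in% c("both", "b_only")) {
      sb <- place(db$chrom, lenb, Lb)
      rb <- to_axis_ranges(db$chrom, sb, sb + lenb, off)
    }
    if (check_conservation) {
      stopifnot(identical(sort(IRanges::width(ra)), sort(IRanges::width(ra_obs))),
                identical(sort(IRanges::width(rb)), sort(IRanges::width(rb_obs))))
    }
    null_counts[i] <- overlap_stat(ra, rb, min_overlap, statistic)
  }
  r <- sum(null_counts >= observed)
  null_sd <- sd(null_counts)
  structure(list(
    observed = observed,
    null_counts = null_counts,
    p_empirical = r / n_perm,
    p_pseudocount = (r + 1) / (n_perm + 1),
    null_mean = mean(null_counts),
    null_sd = null_sd,
    z_score = if (isTRUE(null_sd > 0)) (observed - mean(null_counts)) / null_sd
              else NA_real_,
    config = list(n_perm = n_perm, seed = seed, min_overlap = min_overlap,
                  randomize = randomize, statistic = statistic,
                  masked = !is.null(mask)),
    label_a = a$label, label_b = b$label
  ), class = "perm_test")
}

#' Summary table of a permutation test
#'
#' @param result a `perm_test` from [permutation_test()].
#' @return One-row data frame: `observed`, `null_mean`, `null_sd`,
#'   `z_score` (`NA` when the null is degenerate), `p_empirical` (raw
#'   proportion, may be 0) and `p_pseudocount` (`(r+1)/(n+1)`).
#' @export
null_summary <- function(result) {
  stopifnot(inherits(result, "perm_test"))
  data.frame(observed = result$observed,
             null_mean = result$null_mean,
             null_sd = result$null_sd,
             z_score = result$z_score,
             p_empirical = result$p_empirical,
             p_pseudocount = result$p_pseudocount)
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test of peak overlap (", x$label_a, " vs ", x$label_b,
      ")\n", sep = "")
  cat("  statistic: ", x$config$statistic, ", min overlap ",
      x$config$min_overlap, " bp, ", x$config$n_perm,
      " permutations (", x$config$randomize, ")\n", sep = "")
  cat("  observed = ", x$observed, ", null = ",
      format(round(x$null_mean, 2)), " +/- ",
      format(round(x$null_sd, 2)), "\n", sep = "")
  cat("  p (empirical) = ", format(x$p_empirical),
      ", p (pseudocount) = ", format(signif(x$p_pseudocount, 4)),
      if (is.finite(x$z_score)) paste0(", z = ", format(round(x$z_score, 2))),
      "\n", sep = "")
  invisible(x)
}
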