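#' Repeat-content summary of shared versus unique peaks
#'
#' The headline statistics contrasting the A-side shared and unique
#' partitions of an [intersect_peaks()] result: how many peaks carry at
#' least one telomeric repeat, how many of those carry more than one,
#' median repeats per repeat-bearing peak, each partition's share of all
#' repeat occurrences, and how many peaks pass the tandem filter
#' (equivalently, type IV/V peaks).
#'
#' Medians and the more-than-one percentages are computed within the
#' subpopulation of peaks harbouring at least one repeat, matching the way
#' such distributions are conditioned in practice.
#'
#' @param overlap an `overlap_result` from [intersect_peaks()].
#' @param profiles a `repeat_profiles` data frame covering every A-side
#'   peak (shared and unique).
#' @param min_tandem tandem-stretch threshold in units (default 4).
#' @return A `repeat_content_summary` list; see fields in the details.
#'   `repeat_share_*` are `NA` (and `repeat_share_defined` is `FALSE`)
#'   when no repeat exists anywhere.
#' @export
repeat_content_summary <- function(overlap, profiles, min_tandem = 4) {
  stopifnot(inherits(overlap, "overlap_result"))
  shared_names <- overlap$shared_a$intervals$name
  unique_names <- overlap$unique_a$intervals$name
  idx <- function(nms) {
    i <- match(nms, profiles$peak_name)
    if (anyNA(i))
      stop("no repeat profile for peak '", nms[which(is.na(i))[1]], "'")
    i
  }
  tot_s <- profiles$total[idx(shared_names)]
  tot_u <- profiles$total[idx(unique_names)]
  lt_s <- profiles$longest_tandem[idx(shared_names)]
  lt_u <- profiles$longest_tandem[idx(unique_names)]
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  n_shared <- length(tot_s); n_unique <- length(tot_u)
  n_shared_ge1 <- sum(tot_s >= 1); n_unique_ge1 <- sum(tot_u >= 1)
  n_shared_gt1 <- sum(tot_s > 1); n_unique_eq1 <- sum(tot_u == 1)
  total_repeats <- sum(tot_s) + sum(tot_u)
  n_shared_tandem <- sum(lt_s >= min_tandem)
  n_unique_tandem <- sum(lt_u >= min_tandem)
  structure(list(
    min_tandem = min_tandem,
    n_shared = n_shared, n_unique = n_unique,
    n_shared_ge1 = n_shared_ge1, n_unique_ge1 = n_unique_ge1,
    pct_shared_ge1 = pct(n_shared_ge1, n_shared),
    pct_unique_ge1 = pct(n_unique_ge1, n_unique),
    n_shared_gt1 = n_shared_gt1, n_unique_eq1 = n_unique_eq1,
    pct_shared_gt1 = pct(n_shared_gt1, n_shared_ge1),
    pct_unique_eq1 = pct(n_unique_eq1, n_unique_ge1),
    median_repeats_shared = if (n_shared_ge1) median(tot_s[tot_s >= 1]) else NA_real_,
    median_repeats_unique = if (n_unique_ge1) median(tot_u[tot_u >= 1]) else NA_real_,
    repeat_share_defined = total_repeats > 0,
    repeat_share_shared = if (total_repeats > 0) sum(tot_s) / total_repeats else NA_real_,
    repeat_share_unique = if (total_repeats > 0) sum(tot_u) / total_repeats else NA_real_,
    n_shared_tandem = n_shared_tandem, n_unique_tandem = n_unique_tandem,
    pct_shared_tandem = pct(n_shared_tandem, n_shared),
    pct_shared_no_tandem = pct(n_shared - n_shared_tandem, n_shared),
    pct_unique_tandem = pct(n_unique_tandem, n_unique),
    pct_unique_no_tandem = pct(n_unique - n_unique_tandem, n_unique)
  ), class = "repeat_content_summary")
}

#' @export
print.repeat_content_summary <- function(x, ...) {
  f <- function(v) format(round(v, 1))
  cat("Repeat-content summary (tandem threshold ", x$min_tandem,
      " units)\n", sep = "")
  cat("  shared peaks: ", x$n_shared, "; with >=1 repeat: ", x$n_shared_ge1,
      " (", f(x$pct_shared_ge1), "%)\n", sep = "")
  cat("  unique peaks: ", x$n_unique, "; with >=1 repeat: ", x$n_unique_ge1,
      " (", f(x$pct_unique_ge1), "%)\n", sep = "")
  cat("  >1 repeat among repeat-bearing shared: ", x$n_shared_gt1, " (",
      f(x$pct_shared_gt1), "%), median ", format(x$median_repeats_shared),
      "\n", sep = "")
  cat("  =1 repeat among repeat-bearing unique: ", x$n_unique_eq1, " (",
      f(x$pct_unique_eq1), "%), median ", format(x$median_repeats_unique),
      "\n", sep = "")
  if (isTRUE(x$repeat_share_defined))
    cat("  repeat share: shared ", f(100 * x$repeat_share_shared),
        "% / unique ", f(100 * x$repeat_share_unique), "%\n", sep = "")
  else cat("  repeat share: undefined (no repeats found)\n")
  cat("  tandem filter pass: shared ", x$n_shared_tandem, " (",
      f(x$pct_shared_tandem), "%), unique ", x$n_unique_tandem, " (",
      f(x$pct_unique_tandem), "%)\n", sep = "")
  invisible(x)
}

#' Two-group comparison of repeat counts
#'
#' Two-sided t-test of the group means; Welch (unequal variance) by
#' default, which is the safer choice when the groups differ greatly in
#' size, with the pooled-variance variant available.
#'
#' @param values_a,values_b numeric vectors, each with at least two values
#'   and non-degenerate combined variance.
#' @param labels length-2 character vector naming the groups.
#' @param var_equal use the pooled-variance (Student) form.
#' @return A `group_comparison` list: labels, sizes, means, `t_statistic`,
#'   `df`, `p_value`.
#' @export
compare_groups <- function(values_a, values_b, labels = c("A", "B"),
                           var_equal = FALSE) {
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least two values")
  if (stats::var(values_a) + stats::var(values_b) == 0)
    stop("degenerate variance: both groups are constant")
  tt <- t.test(values_a, values_b, var.equal = var_equal)
  structure(list(group_a_label = labels[1], group_b_label = labels[2],
                 n_a = length(values_a), n_b = length(values_b),
                 mean_a = mean(values_a), mean_b = mean(values_b),
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 var_equal = var_equal),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(if (x$var_equal) "Student" else "Welch", " t-test: ",
      x$group_a_label, " (n=", x$n_a, ", mean=", format(signif(x$mean_a, 4)),
      ") vs ", x$group_b_label, " (n=", x$n_b, ", mean=",
      format(signif(x$mean_b, 4)), ")\n", sep = "")
  cat("  t = ", format(signif(x$t_statistic, 4)), ", df = ",
      format(round(x$df, 2)), ", p = ", format(signif(x$p_value, 4)),
      "\n", sep = "")
  invisible(x)
}

#' Write a machine- and human-readable results bundle
#'
#' Writes `report.json` (versioned schema; absent components are `null`)
#' plus TSV mirrors of whichever components are present. Output is a pure
#' function of the inputs (no timestamps), so re-running an identical
#' analysis reproduces the bundle byte for byte.
#'
#' @param path output directory (created if needed).
#' @param summary a `repeat_content_summary`, or `NULL`.
#' @param comparisons a list of `group_comparison` objects, or `NULL`.
#' @param annotation a breakdown from [annotation_breakdown()], or `NULL`.
#' @param perm a `perm_test`, or `NULL`.
#' @return Named character vector of file paths, invisibly.
#' @export
report <- function(path, summary = NULL, comparisons = NULL,
                   annotation = NULL, perm = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create report directory: ", path)
  files <- c(json = file.path(path, "report.json"))
  doc <- list(schema = "telopeaks-report/1.0",
              summary = if (!is.null(summary)) unclass(summary),
              comparisons = if (!is.null(comparisons))
                lapply(unname(comparisons), unclass),
              annotation_breakdown = annotation,
              permutation = if (!is.null(perm))
                c(list(config = perm$config), null_summary(perm)))
  jsonlite::write_json(doc, files[["json"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null",
                       dataframe = "rows")
  tsv <- function(df, name) {
    p <- file.path(path, name)
    lines <- c(paste0("#", paste(names(df), collapse = "\t")),
               do.call(paste, c(lapply(df, function(col)
                 format(col, scientific = FALSE, trim = TRUE)), sep = "\t")))
    writeLines(lines, p)
    p
  }
  if (!is.null(summary)) {
    s <- unclass(summary)
    files["summary"] <- tsv(data.frame(field = names(s),
                                       value = vapply(s, function(v)
                                         format(v, scientific = FALSE, trim = TRUE), ""),
                                       stringsAsFactors = FALSE),
                            "summary.tsv")
  }
  if (!is.null(comparisons)) {
    cmp <- do.call(rbind, lapply(comparisons, function(x)
      as.data.frame(unclass(x), stringsAsFactors = FALSE)))
    files["comparisons"] <- tsv(cmp, "comparisons.tsv")
  }
  if (!is.null(annotation))
    files["annotation"] <- tsv(annotation, "annotation_breakdown.tsv")
  if (!is.null(perm)) {
    files["permutation"] <- tsv(null_summary(perm), "permutation.tsv")
    files["null_counts"] <- tsv(data.frame(null_count = perm$null_counts),
                                "null_counts.tsv")
  }
  invisible(files)
}
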