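#' Read a BED-family peak file
#'
#' Supports BED3, BED6 and ENCODE narrowPeak (BED6+4). Records are returned
#' in file order; comment (`#`), `track` and `browser` lines are skipped but
#' still count towards the line numbers used in messages and generated
#' names. Unnamed records (missing column 4 or `"."`) receive names
#' `peak_<line#>`. narrowPeak extra columns are retained as metadata
#' columns `signal_value`, `p_value`, `q_value` (kept verbatim as text, so
#' round-trips are byte-faithful) and `summit` (integer offset).
#'
#' @param path file to read.
#' @param dialect one of `"bed3"`, `"bed6"`, `"narrowpeak"`.
#' @param chromsizes optional [chrom_sizes()]; if supplied, unknown
#'   chromosomes are an error (fail fast when validation is possible).
#' @param label label for the resulting set; defaults to the file name.
#' @return A [peak_set()] in file order.
#' @export
read_bed <- function(path, dialect = c("bed6", "bed3", "narrowpeak"),
                     chromsizes = NULL, label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  ncol_needed <- switch(dialect, bed3 = 3L, bed6 = 4L, narrowpeak = 10L)
  if (!length(lines))
    return(peak_set(NULL, label = label, chromsizes = chromsizes))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- vapply(parts, length, 1L)
  bad <- which(nc < ncol_needed)
  if (length(bad))
    stop("line ", lineno[bad[1]], " of ", path, ": expected >= ",
         ncol_needed, " tab-separated columns for dialect '", dialect,
         "', found ", nc[bad[1]])
  col <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, "")
  chrom <- col(1)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop("line ", lineno[bad[1]], " of ", path,
         ": coordinates must be non-negative integers")
  bad <- which(start >= end)
  if (length(bad))
    stop("line ", lineno[bad[1]], " of ", path, ": start >= end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (dialect != "bed3") {
    nm <- col(4)
    unnamed <- is.na(nm) | nm == "." | nm == ""
    nm[unnamed] <- paste0("peak_", lineno[unnamed])
    if (anyDuplicated(nm)) {
      warning("duplicated peak names in ", path, "; suffixing to keep them unique")
      nm <- make.unique(nm, sep = "_dup")
    }
    df$name <- nm
    sc <- col(5)
    df$score <- suppressWarnings(as.numeric(ifelse(is.na(sc) | sc == ".", NA, sc)))
    st <- col(6)
    st[is.na(st) | !(st %in% c("+", "-", "."))] <- "."
    df$strand <- st
  }
  if (dialect == "narrowpeak") {
    df$signal_value <- col(7)
    df$p_value <- col(8)
    df$q_value <- col(9)
    summit <- suppressWarnings(as.integer(col(10)))
    bad <- which(is.na(summit))
    if (length(bad))
      stop("line ", lineno[bad[1]], " of ", path,
           ": narrowPeak summit (column 10) must be an integer")
    df$summit <- summit
  }
  if (anyDuplicated(paste(df$chrom, df$start, df$end)))
    warning("duplicate records (same coordinates) in ", path, "; kept as-is")
  peak_set(df, label = label, chromsizes = chromsizes, sort = FALSE)
}

#' Write a peak set as BED
#'
#' Output is deterministic: canonical (chrom, start, end, name) sort,
#' tab-separated, no trailing whitespace, no header. Re-reading with
#' [read_bed()] recovers the retained columns exactly.
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @param dialect one of `"bed6"`, `"bed3"`, `"narrowpeak"`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path, dialect = c("bed6", "bed3", "narrowpeak")) {
  dialect <- match.arg(dialect)
  validate_peak_set(peaks)
  df <- sort_peaks(peaks)$intervals
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  if (!nrow(df)) return(invisible(path))
  fields <- list(df$chrom, format_bp(df$start), format_bp(df$end))
  if (dialect != "bed3") {
    score <- ifelse(is.na(df$score), "0", format_bp(df$score))
    fields <- c(fields, list(df$name, score, df$strand))
  }
  if (dialect == "narrowpeak") {
    sv <- if (!is.null(df$signal_value)) as.character(df$signal_value) else rep("0", nrow(df))
    pv <- if (!is.null(df$p_value)) as.character(df$p_value) else rep("-1", nrow(df))
    qv <- if (!is.null(df$q_value)) as.character(df$q_value) else rep("-1", nrow(df))
    sm <- if (!is.null(df$summit)) format_bp(df$summit) else rep("-1", nrow(df))
    fields <- c(fields, list(sv, pv, qv, sm))
  }
  writeLines(do.call(paste, c(fields, sep = "\t")), con)
  invisible(path)
}
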