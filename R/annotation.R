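#' Read gene models from BED12
#'
#' Exon blocks are reconstructed from the block fields and validated
#' (consistent `blockCount`, blocks sorted, non-overlapping, first block at
#' the transcript start and last ending at the transcript end). The TSS is
#' the transcript start for `+` genes and the transcript end for `-` genes.
#'
#' @param path BED12 file.
#' @return A `gene_models` data frame: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, plus a list column `exons` of two-column matrices
#'   (absolute `start`, `end` per exon, 0-based half-open).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_gene_models())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    ln <- lineno[i]
    if (length(p) < 12)
      stop("line ", ln, " of ", path, ": BED12 needs 12 columns, found ",
           length(p))
    start <- as.numeric(p[2]); end <- as.numeric(p[3])
    if (is.na(start) || is.na(end) || start < 0 || start >= end)
      stop("line ", ln, " of ", path, ": invalid transcript span")
    strand <- p[6]
    if (!strand %in% c("+", "-"))
      stop("line ", ln, " of ", path, ": gene strand must be '+' or '-'")
    n_blocks <- as.integer(p[10])
    sizes <- as.numeric(strsplit(sub(",$", "", p[11]), ",", fixed = TRUE)[[1]])
    starts <- as.numeric(strsplit(sub(",$", "", p[12]), ",", fixed = TRUE)[[1]])
    if (is.na(n_blocks) || length(sizes) != n_blocks ||
        length(starts) != n_blocks)
      stop("line ", ln, " of ", path,
           ": blockCount does not match blockSizes/blockStarts")
    if (any(is.na(sizes)) || any(is.na(starts)) || any(sizes < 1))
      stop("line ", ln, " of ", path, ": malformed block fields")
    if (starts[1] != 0 || is.unsorted(starts, strictly = TRUE) ||
        any(starts + sizes > end - start) ||
        starts[n_blocks] + sizes[n_blocks] != end - start ||
        (n_blocks > 1 && any(starts[-1] < (starts + sizes)[-n_blocks])))
      stop("line ", ln, " of ", path, ": inconsistent exon blocks")
    rows[[i]] <- list(gene_id = p[4], chrom = p[1], strand = strand,
                      start = start, end = end,
                      exons = cbind(start = start + starts,
                                    end = start + starts + sizes))
  }
  ids <- vapply(rows, `[[`, "", "gene_id")
  if (anyDuplicated(ids))
    stop("duplicated gene ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- data.frame(gene_id = ids,
                    chrom = vapply(rows, `[[`, "", "chrom"),
                    strand = vapply(rows, `[[`, "", "strand"),
                    start = vapply(rows, `[[`, 0, "start"),
                    end = vapply(rows, `[[`, 0, "end"),
                    stringsAsFactors = FALSE)
  out$exons <- lapply(rows, `[[`, "exons")
  class(out) <- c("gene_models", "data.frame")
  out
}

empty_gene_models <- function() {
  out <- data.frame(gene_id = character(0), chrom = character(0),
                    strand = character(0), start = numeric(0),
                    end = numeric(0), stringsAsFactors = FALSE)
  out$exons <- list()
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Write gene models as BED12
#'
#' @param models a `gene_models` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  if (!nrow(models)) { writeLines(character(0), path); return(invisible(path)) }
  lines <- vapply(seq_len(nrow(models)), function(i) {
    ex <- models$exons[[i]]
    sizes <- ex[, "end"] - ex[, "start"]
    starts <- ex[, "start"] - models$start[i]
    paste(models$chrom[i], format_bp(models$start[i]),
          format_bp(models$end[i]), models$gene_id[i], "0",
          models$strand[i], format_bp(models$start[i]),
          format_bp(models$end[i]), "0", length(sizes),
          paste0(paste(format_bp(sizes), collapse = ","), ","),
          paste0(paste(format_bp(starts), collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Transcription start sites of gene models
#'
#' @param models a `gene_models` data frame.
#' @return Numeric vector of TSS coordinates named by gene id
#'   (transcript start for `+` genes, transcript end for `-`).
#' @export
gene_tss <- function(models) {
  setNames(ifelse(models$strand == "+", models$start, models$end),
           models$gene_id)
}

#' Annotate peaks against gene models
#'
#' Each peak's midpoint (`(start + end) / 2`) determines its category with
#' the precedence promoter > TTS > exon > intron > intergenic. Promoter and
#' TTS membership use the strand-oriented distance of the midpoint from the
#' TSS (resp. transcript end), inside the closed window
#' `[-upstream, +downstream]`; exon/intron membership tests the base
#' containing the midpoint against exon blocks and the transcript span.
#' The nearest gene minimises `|midpoint - TSS|` over genes on the peak's
#' chromosome, ties broken by the lexicographically smaller gene id;
#' `tss_distance` is signed and strand-oriented (positive = downstream of
#' the TSS). Peaks on gene-free chromosomes are intergenic with no nearest
#' gene.
#'
#' @param peaks a [peak_set()].
#' @param genes a `gene_models` data frame from [read_gene_models()].
#' @param promoter_window `c(upstream, downstream)` bp around the TSS
#'   (default 1000, 100).
#' @param tts_window `c(upstream, downstream)` bp around the transcript
#'   end (default 100, 1000).
#' @return A `peak_annotation` data frame: `peak_name`, `category`,
#'   `nearest_gene`, `tss_distance`.
#' @export
annotate_peaks <- function(peaks, genes, promoter_window = c(1000, 100),
                           tts_window = c(100, 1000)) {
  stopifnot(inherits(peaks, "peak_set"))
  df <- peaks$intervals
  n <- nrow(df)
  category <- rep("intergenic", n)
  nearest <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  tss_all <- gene_tss(genes)
  for (i in seq_len(n)) {
    gi <- which(genes$chrom == df$chrom[i])
    if (!length(gi)) next
    m <- (df$start[i] + df$end[i]) / 2
    g_strand <- genes$strand[gi]
    tss <- unname(tss_all[gi])
    tes <- ifelse(g_strand == "+", genes$end[gi], genes$start[gi])
    d_tss <- ifelse(g_strand == "+", m - tss, tss - m)
    d_tes <- ifelse(g_strand == "+", m - tes, tes - m)
    b <- floor(m)
    in_exon <- any(vapply(genes$exons[gi], function(ex)
      any(b >= ex[, "start"] & b < ex[, "end"]), TRUE))
    in_span <- any(b >= genes$start[gi] & b < genes$end[gi])
    category[i] <-
      if (any(d_tss >= -promoter_window[1] & d_tss <= promoter_window[2]))
        "promoter_tss"
      else if (any(d_tes >= -tts_window[1] & d_tes <= tts_window[2]))
        "tts"
      else if (in_exon) "exon"
      else if (in_span) "intron"
      else "intergenic"
    o <- order(abs(d_tss), genes$gene_id[gi], method = "radix")[1]
    nearest[i] <- genes$gene_id[gi][o]
    dist[i] <- d_tss[o]
  }
  out <- data.frame(peak_name = df$name, category = category,
                    nearest_gene = nearest, tss_distance = dist,
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_annotation", "data.frame")
  out
}

#' Annotate a single peak
#'
#' @param peak a one-row data frame (or list) with `chrom`, `start`, `end`
#'   and optionally `name`.
#' @inheritParams annotate_peaks
#' @return A one-row `peak_annotation` data frame.
#' @export
annotate_peak <- function(peak, genes, promoter_window = c(1000, 100),
                          tts_window = c(100, 1000)) {
  ps <- peak_set(as.data.frame(as.list(peak), stringsAsFactors = FALSE),
                 label = "peak")
  annotate_peaks(ps, genes, promoter_window, tts_window)
}

#' Category breakdown of annotated peaks
#'
#' @param records a `peak_annotation` data frame.
#' @return Data frame with one row per category (all five always present):
#'   `category`, `count`, `percentage` (percentages sum to 100).
#' @export
annotation_breakdown <- function(records) {
  if (!nrow(records)) stop("no annotation records")
  lv <- c("promoter_tss", "exon", "intron", "tts", "intergenic")
  tab <- table(factor(records$category, levels = lv))
  data.frame(category = lv, count = as.integer(tab),
             percentage = 100 * as.integer(tab) / nrow(records),
             stringsAsFactors = FALSE)
}

#' Overlap of peak-associated genes with an external gene list
#'
#' The peak-associated gene set is the distinct `nearest_gene` values of
#' the records (optionally restricted to peaks within `max_tss_distance`
#' bp of their TSS); it is intersected with e.g. a differential-expression
#' list, returning the intersection and the three Venn counts.
#'
#' @param records a `peak_annotation` data frame.
#' @param de_genes character vector of gene ids (the external list).
#' @param max_tss_distance optional cap on `|tss_distance|` for a peak's
#'   gene to count as associated.
#' @return List with `associated` (sorted gene ids), `intersection`
#'   (sorted), and `counts = c(a_only, b_only, both)`.
#' @export
gene_list_overlap <- function(records, de_genes, max_tss_distance = NULL) {
  keep <- !is.na(records$nearest_gene)
  if (!is.null(max_tss_distance))
    keep <- keep & !is.na(records$tss_distance) &
      abs(records$tss_distance) <= max_tss_distance
  assoc <- sort(unique(records$nearest_gene[keep]))
  de <- sort(unique(as.character(de_genes)))
  both <- intersect(assoc, de)
  list(associated = assoc,
       intersection = both,
       counts = c(a_only = length(assoc) - length(both),
                  b_only = length(de) - length(both),
                  both = length(both)))
}

#' Read a plain-text gene list (one id per line)
#'
#' @param path file with one gene identifier per line; blank lines and
#'   `#` comments are skipped.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
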