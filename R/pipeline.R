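#' End-to-end peak overlap and repeat-content analysis
#'
#' Convenience driver chaining the pipeline stages: optional exclusion
#' filtering (blacklist/subtelomeres), shared/unique intersection
#' partitioning, repeat profiling of the A-side peaks, the repeat-content
#' summary, repeat-count group comparisons, genomic annotation of the
#' shared peaks, gene-list overlap for the tandem-passing shared peaks,
#' and an optional permutation test of the overlap.
#'
#' Exclusion is a pre-filter: when `exclude` is given the partition is
#' computed on the filtered sets, and the unfiltered partition is kept in
#' `$overlap_unfiltered` so both counts are reportable.
#'
#' @param a,b [peak_set()] objects (A is the set whose shared/unique
#'   partition the summaries describe).
#' @param genome FASTA path or named sequence set; `NULL` skips repeat
#'   profiling and everything downstream of it.
#' @param chromsizes a [chrom_sizes()]; required for the permutation test.
#' @param genes optional `gene_models`; enables annotation.
#' @param de_genes optional character vector; enables gene-list overlap.
#' @param exclude optional mask [peak_set()] or list of them.
#' @param min_overlap intersection threshold in bp.
#' @param min_tandem tandem-stretch threshold in units.
#' @param n_perm permutations for the overlap test; 0 skips it.
#' @param seed seed for the permutation test.
#' @param max_tss_distance optional cap for gene association distance.
#' @return A `peak_overlap_analysis` list with components `overlap`,
#'   `overlap_unfiltered`, `profiles`, `summary`, `comparisons`,
#'   `annotation`, `breakdown`, `gene_overlap`, `perm`.
#' @export
peak_overlap_analysis <- function(a, b, genome = NULL, chromsizes = NULL,
                                  genes = NULL, de_genes = NULL,
                                  exclude = NULL, min_overlap = 1,
                                  min_tandem = 4, n_perm = 0, seed = NULL,
                                  max_tss_distance = NULL) {
  overlap_unfiltered <- NULL
  if (!is.null(exclude)) {
    overlap_unfiltered <- intersect_peaks(a, b, min_overlap)
    a <- exclude_regions(a, exclude)
    b <- exclude_regions(b, exclude)
  }
  overlap <- intersect_peaks(a, b, min_overlap)
  profiles <- summary <- comparisons <- annotation <- breakdown <-
    gene_overlap <- perm <- NULL
  if (!is.null(genome)) {
    profiles <- profile_peaks(a, genome, min_tandem = min_tandem)
    summary <- repeat_content_summary(overlap, profiles, min_tandem)
    shared_tot <- profiles$total[match(overlap$shared_a$intervals$name,
                                       profiles$peak_name)]
    unique_tot <- profiles$total[match(overlap$unique_a$intervals$name,
                                       profiles$peak_name)]
    gs <- shared_tot[shared_tot >= 1]; gu <- unique_tot[unique_tot >= 1]
    if (length(gs) >= 2 && length(gu) >= 2 &&
        stats::var(gs) + stats::var(gu) > 0)
      comparisons <- list(repeats_per_peak = compare_groups(
        gs, gu, labels = c("shared", "unique")))
  }
  if (!is.null(genes)) {
    annotation <- annotate_peaks(overlap$shared_a, genes)
    if (nrow(annotation)) breakdown <- annotation_breakdown(annotation)
    if (!is.null(de_genes) && !is.null(profiles)) {
      pass <- filter_min_tandem(profiles, min_tandem)$passing$peak_name
      rec <- annotation[annotation$peak_name %in% pass, , drop = FALSE]
      gene_overlap <- gene_list_overlap(rec, de_genes, max_tss_distance)
    }
  }
  if (n_perm > 0) {
    if (is.null(chromsizes))
      stop("chromsizes is required for the permutation test")
    perm <- permutation_test(a, b, chromsizes, n_perm = n_perm, seed = seed,
                             min_overlap = min_overlap)
  }
  structure(list(overlap = overlap, overlap_unfiltered = overlap_unfiltered,
                 profiles = profiles, summary = summary,
                 comparisons = comparisons, annotation = annotation,
                 breakdown = breakdown, gene_overlap = gene_overlap,
                 perm = perm, min_tandem = min_tandem),
            class = "peak_overlap_analysis")
}

#' @export
print.peak_overlap_analysis <- function(x, ...) {
  cat("peak_overlap_analysis\n")
  print(x$overlap)
  if (!is.null(x$overlap_unfiltered))
    cat("  (before exclusion: ", n_peaks(x$overlap_unfiltered$shared_a),
        " shared)\n", sep = "")
  if (!is.null(x$summary)) print(x$summary)
  if (!is.null(x$breakdown)) {
    cat("Annotation of shared peaks:\n")
    print(x$breakdown, row.names = FALSE)
  }
  if (!is.null(x$gene_overlap))
    cat("Gene-list overlap: ", x$gene_overlap$counts[["both"]],
        " in common (A only ", x$gene_overlap$counts[["a_only"]],
        ", B only ", x$gene_overlap$counts[["b_only"]], ")\n", sep = "")
  if (!is.null(x$perm)) print(x$perm)
  invisible(x)
}

#' Write the report bundle for a pipeline result
#'
#' @param analysis a `peak_overlap_analysis`.
#' @param path output directory.
#' @return Named character vector of file paths, invisibly.
#' @export
write_report <- function(analysis, path) {
  stopifnot(inherits(analysis, "peak_overlap_analysis"))
  report(path, summary = analysis$summary,
         comparisons = analysis$comparisons,
         annotation = analysis$breakdown, perm = analysis$perm)
}
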