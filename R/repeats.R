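#' Telomeric motif pair
#'
#' The forward telomeric hexamer and its reverse complement. Matching is
#' exact (no degenerate units), so occurrences of `TTAGGG` on the plus
#' strand and of `CCCTAA` (a minus-strand array read on the reference)
#' are counted separately and summed per peak.
#'
#' @param forward forward repeat unit (default `"TTAGGG"`).
#' @return A `motif_spec` with fields `forward`, `reverse`, `unit_length`.
#' @export
motif_spec <- function(forward = "TTAGGG") {
  forward <- toupper(as.character(forward)[1])
  if (!nzchar(forward) || grepl("[^ACGT]", forward))
    stop("forward motif must be a non-empty A/C/G/T string")
  reverse <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(forward)))
  structure(list(forward = forward, reverse = reverse,
                 unit_length = nchar(forward)), class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("motif_spec: ", x$forward, " / ", x$reverse,
      " (unit ", x$unit_length, " bp)\n", sep = "")
  invisible(x)
}

# normalise sequence case; optionally treat soft-masked (lowercase) bases
# as unmatchable before uppercasing
prep_seq <- function(seq, respect_softmask = FALSE) {
  seq <- as.character(seq)[1]
  if (respect_softmask) seq <- gsub("[a-z]", "N", seq)
  toupper(seq)
}

#' Exact motif scan
#'
#' All start offsets (0-based) at which `motif` matches `seq` exactly.
#' Matching is case-insensitive unless `respect_softmask = TRUE`, in which
#' case soft-masked (lowercase) bases never match. `N` never matches.
#' Overlapping matches are reported (the telomeric hexamer has no
#' non-trivial self-overlap, so its occurrences are naturally disjoint).
#'
#' @param seq a character scalar over the A/C/G/T/N alphabet.
#' @param motif non-empty motif string.
#' @param respect_softmask treat lowercase bases as unmatchable.
#' @return Strictly increasing integer vector of 0-based offsets.
#' @examples
#' scan_motif("TTAGGGTTAGGG", "TTAGGG")  # 0, 6
#' @export
scan_motif <- function(seq, motif, respect_softmask = FALSE) {
  motif <- as.character(motif)[1]
  if (is.na(motif) || !nzchar(motif)) stop("motif must be non-empty")
  s <- prep_seq(seq, respect_softmask)
  if (nchar(s) < nchar(motif)) return(integer(0))
  m <- Biostrings::matchPattern(toupper(motif), Biostrings::BString(s))
  as.integer(IRanges::start(m)) - 1L
}

#' Count forward and reverse telomeric repeats in a sequence
#'
#' @inheritParams scan_motif
#' @param motif a [motif_spec()].
#' @return Named integer vector `c(forward = , reverse = )`; the peak total
#'   is their sum.
#' @export
count_repeats <- function(seq, motif = motif_spec(), respect_softmask = FALSE) {
  c(forward = length(scan_motif(seq, motif$forward, respect_softmask)),
    reverse = length(scan_motif(seq, motif$reverse, respect_softmask)))
}

# group 0-based offsets into maximal zero-gap runs of one motif
runs_from_offsets <- function(offsets, unit_length) {
  if (!length(offsets))
    return(data.frame(start = integer(0), units = integer(0)))
  grp <- cumsum(c(1L, as.integer(diff(offsets) != unit_length)))
  data.frame(start = offsets[!duplicated(grp)],
             units = as.integer(tabulate(grp)))
}

#' Tandem runs of telomeric repeats
#'
#' A tandem run is a maximal series of occurrences of the *same* motif at
#' exactly unit-length spacing (zero gap); a single intervening base breaks
#' a run, and runs never mix the forward motif with its reverse complement
#' (a genomic telomeric array is strand-uniform; a `TTAGGGCCCTAA` junction
#' is two runs of one unit each). Every motif occurrence belongs to exactly
#' one run.
#'
#' @inheritParams count_repeats
#' @return Data frame with columns `motif` (the unit sequence), `start`
#'   (0-based offset of the run) and `units` (run length in units),
#'   ordered by `start`.
#' @examples
#' tandem_runs(strrep("TTAGGG", 4))            # one run of 4
#' tandem_runs("TTAGGGCCCTAA")                 # two runs of 1
#' @export
tandem_runs <- function(seq, motif = motif_spec(), respect_softmask = FALSE) {
  u <- motif$unit_length
  fwd <- runs_from_offsets(scan_motif(seq, motif$forward, respect_softmask), u)
  rev <- runs_from_offsets(scan_motif(seq, motif$reverse, respect_softmask), u)
  out <- rbind(
    if (nrow(fwd)) data.frame(motif = motif$forward, fwd) else NULL,
    if (nrow(rev)) data.frame(motif = motif$reverse, rev) else NULL)
  if (is.null(out))
    return(data.frame(motif = character(0), start = integer(0),
                      units = integer(0)))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a peak by its repeat content (types I-V)
#'
#' Given the tandem-run lengths of a peak (in units, both motifs pooled):
#' type I has no repeats; type II a single repeat; type III two or more
#' repeats but no run reaching `min_tandem` units; type IV exactly one run
#' of at least `min_tandem` units; type V two or more such runs. The five
#' classes are exhaustive and mutually exclusive.
#'
#' @param run_lengths integer vector of tandem-run lengths in units (one
#'   entry per run; empty for a repeat-free peak).
#' @param total total repeat count; must equal `sum(run_lengths)` (the
#'   default). Supplied explicitly it is cross-checked against the runs.
#' @param min_tandem minimum run length in units for a "tandem stretch"
#'   (default 4, the stable R-loop threshold; 3 is the in-vitro minimum).
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @examples
#' classify_peak(integer(0))     # "I"
#' classify_peak(c(5, 4, 1))     # "V"
#' classify_peak(c(3, 3, 3))     # "III"
#' @export
classify_peak <- function(run_lengths, total = sum(run_lengths),
                          min_tandem = 4) {
  run_lengths <- as.integer(run_lengths)
  if (length(run_lengths) && any(run_lengths < 1))
    stop("run lengths must be positive")
  if (min_tandem < 1) stop("min_tandem must be >= 1")
  if (total != sum(run_lengths))
    stop("inconsistent profile: total (", total,
         ") != sum of run lengths (", sum(run_lengths), ")")
  if (total == 0) return("I")
  if (total == 1) return("II")
  n_ge <- sum(run_lengths >= min_tandem)
  if (n_ge == 0) "III" else if (n_ge == 1) "IV" else "V"
}

#' Repeat profiles for every peak in a set
#'
#' Extracts each peak's reference sequence (`[start, end)` on the plus
#' strand; both motifs are scanned, so the peak's own strand is
#' irrelevant), scans for the forward and reverse telomeric motif, detects
#' tandem runs and classifies the peak.
#'
#' @param peaks a [peak_set()].
#' @param genome a FASTA path or a named `Biostrings::BStringSet` /
#'   character vector of chromosome sequences.
#' @param min_tandem tandem-stretch threshold in units (default 4).
#' @param motif a [motif_spec()].
#' @param respect_softmask treat lowercase genome bases as unmatchable.
#' @return A `repeat_profiles` data frame: `peak_name`, `chrom`, `start`,
#'   `end`, `count_fwd`, `count_rev`, `total`, `longest_tandem`,
#'   `n_runs_ge_min`, `peak_type`, and a list column `runs` of per-run unit
#'   counts.
#' @export
profile_peaks <- function(peaks, genome, min_tandem = 4,
                          motif = motif_spec(), respect_softmask = FALSE) {
  stopifnot(inherits(peaks, "peak_set"))
  seqs <- load_genome(genome)
  df <- peaks$intervals
  missing <- setdiff(unique(df$chrom), names(seqs))
  if (length(missing))
    stop("chromosome(s) missing from genome: ",
         paste(missing, collapse = ", "))
  widths <- setNames(Biostrings::width(seqs), names(seqs))
  over <- which(df$end > widths[df$chrom])
  if (length(over))
    stop("peak '", df$name[over[1]], "' is out of bounds on ",
         df$chrom[over[1]])
  n <- nrow(df)
  count_fwd <- count_rev <- longest <- n_ge <- integer(n)
  type <- character(n)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- as.character(Biostrings::subseq(seqs[[df$chrom[i]]],
                                         start = df$start[i] + 1,
                                         end = df$end[i]))
    tr <- tandem_runs(s, motif, respect_softmask)
    count_fwd[i] <- sum(tr$units[tr$motif == motif$forward])
    count_rev[i] <- sum(tr$units[tr$motif == motif$reverse])
    runs[[i]] <- tr$units
    longest[i] <- if (nrow(tr)) max(tr$units) else 0L
    n_ge[i] <- sum(tr$units >= min_tandem)
    type[i] <- classify_peak(tr$units, min_tandem = min_tandem)
  }
  out <- data.frame(peak_name = df$name, chrom = df$chrom,
                    start = df$start, end = df$end,
                    count_fwd = count_fwd, count_rev = count_rev,
                    total = count_fwd + count_rev,
                    longest_tandem = longest, n_runs_ge_min = n_ge,
                    peak_type = type, stringsAsFactors = FALSE)
  out$runs <- runs
  attr(out, "min_tandem") <- min_tandem
  class(out) <- c("repeat_profiles", "data.frame")
  out
}

# accept a FASTA path, BStringSet or named character vector; FASTA names
# are trimmed at the first whitespace
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readBStringSet(genome)
  if (is.character(genome)) genome <- Biostrings::BStringSet(genome)
  if (!methods::is(genome, "XStringSet"))
    stop("genome must be a FASTA path or a named sequence set")
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Partition profiles by the tandem filter
#'
#' Splits profiles into those with a tandem stretch of at least
#' `min_tandem` units (equivalently, peak types IV and V) and the rest.
#'
#' @param profiles a `repeat_profiles` data frame from [profile_peaks()].
#' @param min_tandem threshold in units (default 4).
#' @return List with elements `passing` and `failing`.
#' @export
filter_min_tandem <- function(profiles, min_tandem = 4) {
  pass <- profiles$longest_tandem >= min_tandem
  list(passing = profiles[pass, , drop = FALSE],
       failing = profiles[!pass, , drop = FALSE])
}

#' Write repeat profiles as a headered TSV
#'
#' @param profiles a `repeat_profiles` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  cols <- c("peak_name", "chrom", "start", "end", "count_fwd", "count_rev",
            "total", "longest_tandem", "n_runs_ge_min", "peak_type")
  header <- paste0("#", paste(c(cols, "runs"), collapse = "\t"))
  runs <- vapply(profiles$runs, function(r) paste(r, collapse = ","), "")
  body <- do.call(paste, c(lapply(cols, function(cn)
    format_bp(profiles[[cn]])), list(runs), sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
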