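# Independent brute-force oracles and small random-instance generators.
# These deliberately avoid the package's own code paths (no IRanges, no
# Biostrings) so that agreement is a genuine cross-check.

# all offsets (0-based) where motif matches seq exactly, by sliding window
naive_scan <- function(seq, motif) {
  seq <- toupper(seq)
  motif <- toupper(motif)
  n <- nchar(seq)
  k <- nchar(motif)
  if (n < k) return(integer(0))
  idx <- seq_len(n - k + 1)
  idx[substring(seq, idx, idx + k - 1) == motif] - 1L
}

# maximal zero-gap runs from naive offsets; returns units per run
naive_runs <- function(seq, motif) {
  off <- naive_scan(seq, motif)
  if (!length(off)) return(integer(0))
  lens <- integer(0)
  cur <- 1L
  for (i in seq_along(off)[-1]) {
    if (off[i] - off[i - 1] == nchar(motif)) cur <- cur + 1L
    else { lens <- c(lens, cur); cur <- 1L }
  }
  c(lens, cur)
}

# all-pairs overlap partition on plain data frames (chrom, start, end, name)
brute_partition <- function(da, db, min_overlap = 1) {
  shared_a <- character(0); shared_b <- character(0)
  pairs <- list()
  for (i in seq_len(nrow(da))) for (j in seq_len(nrow(db))) {
    if (da$chrom[i] != db$chrom[j]) next
    ov <- min(da$end[i], db$end[j]) - max(da$start[i], db$start[j])
    if (ov >= min_overlap) {
      shared_a <- c(shared_a, da$name[i])
      shared_b <- c(shared_b, db$name[j])
      pairs[[length(pairs) + 1L]] <- data.frame(
        name_a = da$name[i], name_b = db$name[j], overlap = ov,
        stringsAsFactors = FALSE)
    }
  }
  list(shared_a = sort(unique(shared_a)), shared_b = sort(unique(shared_b)),
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(name_a = character(0), name_b = character(0),
                    overlap = numeric(0)))
}

# names of peaks surviving whole-peak exclusion, by brute force
brute_exclude <- function(dp, dm) {
  keep <- logical(nrow(dp))
  for (i in seq_len(nrow(dp))) {
    hit <- FALSE
    for (j in seq_len(nrow(dm))) {
      if (dp$chrom[i] != dm$chrom[j]) next
      if (min(dp$end[i], dm$end[j]) - max(dp$start[i], dm$start[j]) >= 1) {
        hit <- TRUE; break
      }
    }
    keep[i] <- !hit
  }
  sort(dp$name[keep])
}

# random interval table on a few chromosomes
random_intervals <- function(n, chroms = c("chr1", "chr2", "chr3"),
                             L = 10000, max_len = 400, prefix = "p") {
  start <- floor(runif(n) * (L - max_len))
  len <- 1 + floor(runif(n) * max_len)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             name = sprintf("%s%04d", prefix, seq_len(n)),
             stringsAsFactors = FALSE)
}

# random A/C/G/T sequence, optionally with N
random_seq <- function(n, with_n = FALSE) {
  ab <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(ab, n, replace = TRUE), collapse = "")
}

# background sequence containing neither motif, certified by the naive
# oracle (re-drawn until clean)
clean_background <- function(n, motifs = c("TTAGGG", "CCCTAA")) {
  repeat {
    s <- random_seq(n)
    if (!length(unlist(lapply(motifs, naive_scan, seq = s)))) return(s)
  }
}

# Welch t statistic and two-sided p, straight from the textbook formulas
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small synth_config suitable for fast tests; overrides win over defaults
test_config <- function(...) {
  args <- list(chrom_lengths = setNames(rep(2e5, 3), paste0("chr", 1:3)),
               n_arrays = 10, n_peaks_a = 60, n_peaks_b = 60,
               subtel_margin = 2e4, n_genes = 8,
               gene_length = c(3000, 8000), seed = 101)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}
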