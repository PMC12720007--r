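#' Configuration for a synthetic fixture
#'
#' Defines a desk-scale genome with planted tandem telomeric arrays, two
#' peak sets with a controlled designed overlap fraction, repeat enrichment
#' concentrated in the designed shared peaks, and a toy gene model. The
#' whole fixture is a pure function of this configuration (including the
#' seed).
#'
#' @param chrom_lengths chromosome lengths in bp; named, or auto-named
#'   `chr1..chrN` (default five chromosomes of 2 Mb).
#' @param n_arrays number of planted telomeric arrays (default 40).
#' @param array_units `c(min, max)` tandem unit count per array, drawn
#'   uniformly (default 1-12).
#' @param strand_mix probability an array uses the reverse-complement
#'   motif (default 0.5).
#' @param n_peaks_a,n_peaks_b peak counts per set (default 500 each).
#' @param peak_length `c(min, max)` peak length in bp, uniform
#'   (default 150-1000).
#' @param target_overlap_fraction fraction of A peaks forced to overlap a
#'   B peak (default 0.03).
#' @param fraction_shared_on_arrays probability a forced-overlap pair is
#'   centred on a planted array (default 0.25).
#' @param gc_background background GC content (default 0.42, mouse-like).
#' @param n_genes gene count (default 60).
#' @param gene_length `c(min, max)` gene length in bp.
#' @param exon_count `c(min, max)` exons per gene.
#' @param seed integer seed.
#' @param subtel_margin subtelomere margin in bp avoided by arrays
#'   (default 500 kb).
#' @param arrays_in_margins place arrays *inside* the subtelomeric margins
#'   instead of avoiding them (exercises the exclusion path).
#' @param exact_bookkeeping reject chance (non-designed) A-B overlaps so
#'   the designed overlap count is exactly the realized one.
#' @param min_array_gap minimum distance in bp between planted arrays;
#'   must be at least the maximum peak length so a peak centred on one
#'   array can never touch another.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(chrom_lengths = setNames(rep(2e6, 5),
                                                  paste0("chr", 1:5)),
                         n_arrays = 40, array_units = c(1, 12),
                         strand_mix = 0.5,
                         n_peaks_a = 500, n_peaks_b = 500,
                         peak_length = c(150, 1000),
                         target_overlap_fraction = 0.03,
                         fraction_shared_on_arrays = 0.25,
                         gc_background = 0.42,
                         n_genes = 60, gene_length = c(5000, 30000),
                         exon_count = c(2, 6),
                         seed = 1, subtel_margin = 5e5,
                         arrays_in_margins = FALSE,
                         exact_bookkeeping = FALSE,
                         min_array_gap = 2000) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  cfg <- list(chrom_lengths = chrom_lengths, n_arrays = n_arrays,
              array_units = array_units, strand_mix = strand_mix,
              n_peaks_a = n_peaks_a, n_peaks_b = n_peaks_b,
              peak_length = peak_length,
              target_overlap_fraction = target_overlap_fraction,
              fraction_shared_on_arrays = fraction_shared_on_arrays,
              gc_background = gc_background, n_genes = n_genes,
              gene_length = gene_length, exon_count = exon_count,
              seed = seed, subtel_margin = subtel_margin,
              arrays_in_margins = arrays_in_margins,
              exact_bookkeeping = exact_bookkeeping,
              min_array_gap = min_array_gap)
  for (f in c("strand_mix", "target_overlap_fraction",
              "fraction_shared_on_arrays", "gc_background"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (array_units[1] < 1 || array_units[2] < array_units[1])
    stop("array_units must be an increasing positive range")
  if (peak_length[1] < 1 || peak_length[2] < peak_length[1])
    stop("peak_length must be an increasing positive range")
  if (min_array_gap < peak_length[2])
    stop("min_array_gap must be >= the maximum peak length")
  d <- round(cfg$target_overlap_fraction * cfg$n_peaks_a)
  if (round(cfg$fraction_shared_on_arrays * d) > cfg$n_arrays)
    stop("not enough arrays for the designed on-array pairs")
  structure(cfg, class = "synth_config")
}

# base codes and sampling probabilities for the background
.base_chars <- c(65L, 67L, 71L, 84L)  # A C G T
.base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
.motif_codes <- function(motif) match(utf8ToInt(motif), .base_chars)

#' Generate the synthetic genome with planted telomeric arrays
#'
#' Background sequence is i.i.d. at the configured GC content; any
#' accidental occurrence of either telomeric motif is re-rolled locally
#' until the background is verifiably motif-free, then arrays are planted
#' by overwriting at recorded coordinates (pairwise separated by at least
#' `min_array_gap` bp and, unless `arrays_in_margins`, outside the
#' subtelomeric margins). After planting, the scanner is run over every
#' chromosome to confirm that the realized runs equal the planted arrays
#' exactly.
#'
#' @param config a [synth_config()].
#' @param seed optional seed; when `NULL` the current RNG state is used
#'   (as [write_fixture()] does after seeding once).
#' @return List with `seqs` (named character vector of chromosome
#'   sequences) and `arrays` (data frame `array_id`, `chrom`, `start`,
#'   `end`, `motif`, `units`).
#' @export
make_genome <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  motif <- motif_spec()
  probs <- .base_probs(config$gc_background)
  lens <- config$chrom_lengths
  seqs <- setNames(vector("character", length(lens)), names(lens))
  code_vecs <- setNames(vector("list", length(lens)), names(lens))
  for (chr in names(lens)) {
    L <- lens[[chr]]
    v <- sample.int(4L, L, replace = TRUE, prob = probs)
    s <- intToUtf8(.base_chars[v])
    # local re-roll of accidental motif hits until the background is clean
    repeat {
      hits <- c(scan_motif(s, motif$forward), scan_motif(s, motif$reverse))
      if (!length(hits)) break
      for (p in hits)
        v[(p + 1):(p + motif$unit_length)] <-
          sample.int(4L, motif$unit_length, replace = TRUE, prob = probs)
      s <- intToUtf8(.base_chars[v])
    }
    code_vecs[[chr]] <- v
    seqs[[chr]] <- s
  }
  arrays <- place_arrays(config)
  for (i in seq_len(nrow(arrays))) {
    unit <- arrays$motif[i]
    codes <- rep(.motif_codes(unit), arrays$units[i])
    chr <- arrays$chrom[i]
    code_vecs[[chr]][(arrays$start[i] + 1):(arrays$end[i])] <- codes
  }
  for (chr in unique(arrays$chrom))
    seqs[[chr]] <- intToUtf8(.base_chars[code_vecs[[chr]]])
  # cross-check: the realized runs must equal the planted arrays exactly
  for (chr in names(lens)) {
    tr <- tandem_runs(seqs[[chr]], motif)
    want <- arrays[arrays$chrom == chr, , drop = FALSE]
    want <- want[order(want$start), , drop = FALSE]
    if (nrow(tr) != nrow(want) ||
        (nrow(tr) && !(all(tr$start == want$start) &&
                       all(tr$units == want$units) &&
                       all(tr$motif == want$motif))))
      stop("internal error: planted arrays on ", chr,
           " not recovered by the scanner")
  }
  list(seqs = seqs, arrays = arrays)
}

# choose array coordinates subject to margin and gap constraints
place_arrays <- function(config) {
  motif <- motif_spec()
  lens <- config$chrom_lengths
  margin <- config$subtel_margin
  n <- config$n_arrays
  out <- data.frame(array_id = character(0), chrom = character(0),
                    start = numeric(0), end = numeric(0),
                    motif = character(0), units = integer(0),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  units <- config$array_units[1] +
    floor(runif(n) * (config$array_units[2] - config$array_units[1] + 1))
  use_rev <- runif(n) < config$strand_mix
  chroms <- character(n); starts <- numeric(n)
  placed <- list()
  for (i in seq_len(n)) {
    alen <- units[i] * motif$unit_length
    ok <- FALSE
    for (try in seq_len(1000)) {
      chr <- sample(names(lens), 1, prob = unname(lens))
      L <- lens[[chr]]
      if (config$arrays_in_margins) {
        m <- min(margin, floor(L / 2))
        if (m < alen) next
        side <- sample(c("p", "q"), 1)
        s <- if (side == "p") floor(runif(1) * (m - alen + 1))
             else L - m + floor(runif(1) * (m - alen + 1))
      } else {
        lo <- margin; hi <- L - margin - alen
        if (hi < lo) next
        s <- lo + floor(runif(1) * (hi - lo + 1))
      }
      prev <- placed[[chr]]
      if (!is.null(prev) &&
          any(s < prev[, 2] + config$min_array_gap &
              s + alen + config$min_array_gap > prev[, 1])) next
      chroms[i] <- chr; starts[i] <- s
      placed[[chr]] <- rbind(prev, c(s, s + alen))
      ok <- TRUE
      break
    }
    if (!ok)
      stop("cannot place array ", i,
           " without violating gap/margin constraints")
  }
  data.frame(array_id = sprintf("array_%03d", seq_len(n)),
             chrom = chroms, start = starts,
             end = starts + units * motif$unit_length,
             motif = ifelse(use_rev, motif$reverse, motif$forward),
             units = as.integer(units), stringsAsFactors = FALSE)
}

# TRUE if interval [s, e) overlaps any row of df restricted to chrom
overlaps_any <- function(chrom, s, e, df) {
  if (is.null(df) || !nrow(df)) return(FALSE)
  any(df$chrom == chrom & df$start < e & df$end > s)
}

#' Generate the two peak sets with designed overlaps
#'
#' `round(target_overlap_fraction * n_peaks_a)` A peaks are forced to
#' overlap a B peak by construction; of those, a
#' `fraction_shared_on_arrays` share is centred on planted arrays (both
#' pair members fully contain the array). All remaining peaks are placed
#' uniformly, always avoiding arrays and the designed pairs; under
#' `exact_bookkeeping` they additionally avoid the opposite set entirely,
#' so the realized shared count equals the designed one. The realized
#' overlap (which may exceed the target by chance collisions otherwise)
#' is recorded.
#'
#' @param config a [synth_config()].
#' @param genome result of [make_genome()] (for the array coordinates).
#' @param seed optional seed.
#' @return List with peak sets `a` (label TERRA) and `b` (label RLOOP),
#'   `designed_pairs`, `peak_on_array`, and `realized` bookkeeping.
#' @export
make_peaks <- function(config, genome, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  lens <- config$chrom_lengths
  cs <- chrom_sizes(lens)
  arrays <- genome$arrays
  arr_df <- if (nrow(arrays))
    data.frame(chrom = arrays$chrom, start = arrays$start,
               end = arrays$end, stringsAsFactors = FALSE) else NULL
  draw_len <- function(n = 1)
    config$peak_length[1] +
      floor(runif(n) * (config$peak_length[2] - config$peak_length[1] + 1))
  pick_chrom <- function() sample(names(lens), 1, prob = unname(lens))
  d <- round(config$target_overlap_fraction * config$n_peaks_a)
  n_on <- round(config$fraction_shared_on_arrays * d)
  arr_pick <- if (n_on) sample(seq_len(nrow(arrays)), n_on) else integer(0)
  a_rows <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), name = character(0),
                       stringsAsFactors = FALSE)
  b_rows <- a_rows
  on_array <- data.frame(peak = character(0), array_id = character(0),
                         stringsAsFactors = FALSE)
  pairs <- data.frame(name_a = character(0), name_b = character(0),
                      array_id = character(0), stringsAsFactors = FALSE)
  # a placement containing the array, clamped to the chromosome
  contain_array <- function(astart, alen, plen, L) {
    s <- astart - floor((plen - alen) / 2)
    s <- max(0, min(s, L - plen))
    if (s > astart || s + plen < astart + alen)
      s <- max(0, min(astart, L - plen))
    s
  }
  for (i in seq_len(d)) {
    nm_a <- sprintf("terra_%04d", i)
    nm_b <- sprintf("rloop_%04d", i)
    if (i <= n_on) {
      k <- arr_pick[i]
      chr <- arrays$chrom[k]; L <- lens[[chr]]
      alen <- arrays$end[k] - arrays$start[k]
      la <- max(draw_len(), alen + 40)
      lb <- max(draw_len(), alen + 20)
      sa <- contain_array(arrays$start[k], alen, la, L)
      sb <- contain_array(arrays$start[k], alen, lb, L)
      a_rows[nrow(a_rows) + 1L, ] <- list(chr, sa, sa + la, nm_a)
      b_rows[nrow(b_rows) + 1L, ] <- list(chr, sb, sb + lb, nm_b)
      on_array[nrow(on_array) + 1L, ] <- list(nm_a, arrays$array_id[k])
      on_array[nrow(on_array) + 1L, ] <- list(nm_b, arrays$array_id[k])
      pairs[nrow(pairs) + 1L, ] <- list(nm_a, nm_b, arrays$array_id[k])
    } else {
      ok <- FALSE
      for (try in seq_len(1000)) {
        la <- draw_len(); lb <- draw_len()
        chr <- pick_chrom(); L <- lens[[chr]]
        if (L < la || L < lb) next
        sa <- floor(runif(1) * (L - la + 1))
        if (overlaps_any(chr, sa, sa + la, arr_df) ||
            overlaps_any(chr, sa, sa + la, a_rows) ||
            overlaps_any(chr, sa, sa + la, b_rows)) next
        o <- 1 + floor(runif(1) * min(la, lb))
        sb <- if (runif(1) < 0.5) sa - lb + o else sa + la - o
        sb <- max(0, min(sb, L - lb))
        if (min(sa + la, sb + lb) - max(sa, sb) < 1) next
        bb <- b_rows
        if (overlaps_any(chr, sb, sb + lb, arr_df) ||
            overlaps_any(chr, sb, sb + lb, bb)) next
        a_rows[nrow(a_rows) + 1L, ] <- list(chr, sa, sa + la, nm_a)
        b_rows[nrow(b_rows) + 1L, ] <- list(chr, sb, sb + lb, nm_b)
        pairs[nrow(pairs) + 1L, ] <- list(nm_a, nm_b, NA_character_)
        ok <- TRUE
        break
      }
      if (!ok) stop("cannot place designed pair ", i, " (density infeasible)")
    }
  }
  n_designed <- nrow(a_rows)
  place_rest <- function(rows, n_total, prefix, other_rows) {
    for (i in seq(nrow(rows) + 1L, length.out = n_total - nrow(rows))) {
      nm <- sprintf("%s_%04d", prefix, i)
      ok <- FALSE
      for (try in seq_len(1000)) {
        len <- draw_len()
        chr <- pick_chrom(); L <- lens[[chr]]
        if (L < len) next
        s <- floor(runif(1) * (L - len + 1))
        if (overlaps_any(chr, s, s + len, arr_df)) next
        # never disturb the designed pairs
        if (overlaps_any(chr, s, s + len, a_rows[seq_len(n_designed), ]) ||
            overlaps_any(chr, s, s + len, b_rows[seq_len(n_designed), ])) next
        if (config$exact_bookkeeping &&
            overlaps_any(chr, s, s + len, other_rows())) next
        rows[nrow(rows) + 1L, ] <- list(chr, s, s + len, nm)
        ok <- TRUE
        break
      }
      if (!ok) stop("cannot place peak ", nm, " (density infeasible)")
    }
    rows
  }
  a_rows <- place_rest(a_rows, config$n_peaks_a, "terra", function() b_rows)
  b_rows <- place_rest(b_rows, config$n_peaks_b, "rloop", function() a_rows)
  a <- peak_set(a_rows, label = "TERRA", chromsizes = cs)
  b <- peak_set(b_rows, label = "RLOOP", chromsizes = cs)
  res <- intersect_peaks(a, b)
  realized <- list(shared_a = n_peaks(res$shared_a),
                   designed = n_designed,
                   fraction = n_peaks(res$shared_a) / config$n_peaks_a)
  if (config$exact_bookkeeping && realized$shared_a != n_designed)
    stop("internal error: exact bookkeeping violated (",
         realized$shared_a, " shared vs ", n_designed, " designed)")
  list(a = a, b = b, designed_pairs = pairs, peak_on_array = on_array,
       realized = realized)
}

#' Generate a toy gene model set
#'
#' Non-overlapping multi-exon genes on both strands, with exon/intron
#' segment lengths of at least 20 bp.
#'
#' @param config a [synth_config()].
#' @param seed optional seed.
#' @return A `gene_models` data frame.
#' @export
make_genes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  lens <- config$chrom_lengths
  n <- config$n_genes
  if (!n) return(empty_gene_models())
  placed <- NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(1000)) {
      glen <- config$gene_length[1] +
        floor(runif(1) * (config$gene_length[2] - config$gene_length[1] + 1))
      chr <- sample(names(lens), 1, prob = unname(lens))
      L <- lens[[chr]]
      if (L < glen + 2) next
      s <- floor(runif(1) * (L - glen + 1))
      if (overlaps_any(chr, s - 500, s + glen + 500, placed)) next
      k <- config$exon_count[1] +
        floor(runif(1) * (config$exon_count[2] - config$exon_count[1] + 1))
      nseg <- 2 * k - 1
      if (glen < nseg * 20) next
      w <- runif(nseg)
      seg <- 20 + floor(w / sum(w) * (glen - 20 * nseg))
      seg[nseg] <- glen - sum(seg[-nseg])
      bounds <- cumsum(c(0, seg))
      ex <- cbind(start = s + bounds[seq(1, nseg, by = 2)],
                  end = s + bounds[seq(1, nseg, by = 2) + 1])
      rows[[i]] <- list(gene_id = sprintf("gene_%03d", i), chrom = chr,
                        strand = if (runif(1) < 0.5) "+" else "-",
                        start = s, end = s + glen, exons = ex)
      placed <- rbind(placed, data.frame(chrom = chr, start = s,
                                         end = s + glen,
                                         stringsAsFactors = FALSE))
      ok <- TRUE
      break
    }
    if (!ok) stop("cannot place gene ", i, " (infeasible gene count)")
  }
  out <- data.frame(gene_id = vapply(rows, `[[`, "", "gene_id"),
                    chrom = vapply(rows, `[[`, "", "chrom"),
                    strand = vapply(rows, `[[`, "", "strand"),
                    start = vapply(rows, `[[`, 0, "start"),
                    end = vapply(rows, `[[`, 0, "end"),
                    stringsAsFactors = FALSE)
  out$exons <- lapply(rows, `[[`, "exons")
  class(out) <- c("gene_models", "data.frame")
  out
}

# matrix-form category assignment used for the ground truth: same window
# definitions as annotate_peaks but computed by a different route
design_categories <- function(peaks, genes, promoter_window = c(1000, 100),
                              tts_window = c(100, 1000)) {
  df <- peaks$intervals
  m <- (df$start + df$end) / 2
  b <- floor(m)
  out <- rep("intergenic", nrow(df))
  if (!nrow(genes))
    return(data.frame(peak = df$name, category = out,
                      stringsAsFactors = FALSE))
  sgn <- ifelse(genes$strand == "+", 1, -1)
  tss <- unname(gene_tss(genes))
  tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  same <- outer(df$chrom, genes$chrom, "==")
  d_tss <- sweep(outer(m, tss, "-"), 2, sgn, "*")
  d_tes <- sweep(outer(m, tes, "-"), 2, sgn, "*")
  prom <- same & d_tss >= -promoter_window[1] & d_tss <= promoter_window[2]
  tts <- same & d_tes >= -tts_window[1] & d_tes <= tts_window[2]
  exon <- matrix(FALSE, nrow(df), nrow(genes))
  for (g in seq_len(nrow(genes))) {
    ex <- genes$exons[[g]]
    exon[, g] <- same[, g] &
      vapply(b, function(bb) any(bb >= ex[, "start"] & bb < ex[, "end"]), TRUE)
  }
  span <- same & outer(b, genes$start, ">=") & outer(b, genes$end, "<")
  out[rowSums(span) > 0] <- "intron"
  out[rowSums(exon) > 0] <- "exon"
  out[rowSums(tts) > 0] <- "tts"
  out[rowSums(prom) > 0] <- "promoter_tss"
  data.frame(peak = df$name, category = out, stringsAsFactors = FALSE)
}

#' Write a complete synthetic fixture
#'
#' Generates genome, peaks and genes under a single seed and writes a
#' self-describing fixture directory: `genome.fa`, `a.bed`, `b.bed`,
#' `genes.bed12`, `chrom.sizes` and `truth.json` (ground truth sufficient
#' to predict the pipeline's bookkeeping). A partial write removes the
#' directory and raises an error.
#'
#' @param config a [synth_config()].
#' @param dir output directory.
#' @return Invisibly, a list with `dir`, the file `paths`, the `truth`
#'   record and the `config`.
#' @export
write_fixture <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  created <- !dir.exists(dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(dir, recursive = TRUE))
  set.seed(config$seed)
  genome <- make_genome(config)
  pk <- make_peaks(config, genome)
  genes <- make_genes(config)
  categories <- design_categories(pk$a, genes)
  paths <- c(genome = file.path(dir, "genome.fa"),
             a = file.path(dir, "a.bed"),
             b = file.path(dir, "b.bed"),
             genes = file.path(dir, "genes.bed12"),
             chromsizes = file.path(dir, "chrom.sizes"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(genome$seqs),
                              paths[["genome"]], width = 70)
  write_bed(pk$a, paths[["a"]], "bed6")
  write_bed(pk$b, paths[["b"]], "bed6")
  write_gene_models(genes, paths[["genes"]])
  write_chrom_sizes(chrom_sizes(config$chrom_lengths), paths[["chromsizes"]])
  truth <- list(
    schema = "telopeaks-truth/1.0",
    chrom_lengths = as.list(config$chrom_lengths),
    arrays = genome$arrays,
    designed_pairs = pk$designed_pairs,
    peak_on_array = pk$peak_on_array,
    realized = pk$realized,
    categories = categories,
    genes = data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                       strand = genes$strand,
                       tss = unname(gene_tss(genes)),
                       stringsAsFactors = FALSE),
    config = unclass(config)[setdiff(names(unclass(config)),
                                     "chrom_lengths")])
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns",
                       na = "null")
  ok <- TRUE
  invisible(list(dir = dir, paths = paths, truth = truth, config = config))
}

#' Read a fixture directory back
#'
#' @param dir a directory written by [write_fixture()].
#' @return List with `a`, `b` ([peak_set()]s), `chromsizes`, `genes`,
#'   `genome` (FASTA path) and the parsed `truth`.
#' @export
read_fixture <- function(dir) {
  cs <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  list(a = read_bed(file.path(dir, "a.bed"), "bed6", cs, label = "TERRA"),
       b = read_bed(file.path(dir, "b.bed"), "bed6", cs, label = "RLOOP"),
       chromsizes = cs,
       genes = read_gene_models(file.path(dir, "genes.bed12")),
       genome = file.path(dir, "genome.fa"),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
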