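bed12_line <- function(chrom, start, end, id, strand, exons) {
  sizes <- exons[, 2] - exons[, 1]
  starts <- exons[, 1] - start
  paste(chrom, start, end, id, 0, strand, start, end, 0, nrow(exons),
        paste0(paste(sizes, collapse = ","), ","),
        paste0(paste(starts, collapse = ","), ","), sep = "\t")
}

two_exon_minus <- function() {
  # minus-strand gene spanning [0, 1000) with exons (0,200) and (800,1000)
  p <- withr::local_tempfile(
    lines = bed12_line("chr1", 0, 1000, "gA", "-",
                       rbind(c(0, 200), c(800, 1000))),
    .local_envir = parent.frame())
  read_gene_models(p)
}

test_that("BED12 gene models reconstruct exons, TSS and introns", {
  p <- withr::local_tempfile(
    lines = bed12_line("chr1", 0, 1000, "g1", "+", rbind(c(0, 1000))))
  g <- read_gene_models(p)
  expect_equal(nrow(g), 1)
  expect_equal(unname(gene_tss(g)), 0)
  g2 <- two_exon_minus()
  expect_equal(unname(gene_tss(g2)), 1000)
  expect_equal(g2$exons[[1]][, "end"], c(200, 1000))
  # the intron is (200, 800): a midpoint there is neither exon nor outside
  empty <- withr::local_tempfile(lines = character(0))
  expect_equal(nrow(read_gene_models(empty)), 0)
})

test_that("inconsistent BED12 block fields fail with the line number", {
  bad_count <- withr::local_tempfile(
    lines = c(bed12_line("chr1", 0, 300, "ok", "+", rbind(c(0, 300))),
              "chr1\t0\t1000\tbad\t0\t+\t0\t1000\t0\t2\t100,\t0,"))
  expect_error(read_gene_models(bad_count), "line 2")
  bad_span <- withr::local_tempfile(
    lines = "chr1\t0\t1000\tbad\t0\t+\t0\t1000\t0\t1\t900,\t0,")
  expect_error(read_gene_models(bad_span), "inconsistent exon blocks")
  dup <- withr::local_tempfile(
    lines = rep(bed12_line("chr1", 0, 300, "g", "+", rbind(c(0, 300))), 2))
  expect_error(read_gene_models(dup), "duplicated gene ids")
})

test_that("gene models survive a write/read round trip", {
  g <- two_exon_minus()
  p <- withr::local_tempfile()
  write_gene_models(g, p)
  back <- read_gene_models(p)
  expect_equal(back$gene_id, g$gene_id)
  expect_equal(back$exons, g$exons)
})

test_that("midpoint categories follow the documented precedence", {
  g <- two_exon_minus()   # minus strand, TSS at 1000, TTS at 0
  rec <- function(start, end)
    annotate_peak(list(chrom = "chr1", start = start, end = end, name = "p"),
                  g)
  # midpoint 500 bp upstream of the TSS (i.e. at 1500 genomic)
  expect_equal(rec(1400, 1600)$category, "promoter_tss")
  expect_equal(rec(400, 600)$category, "intron")     # midpoint 500
  expect_equal(rec(840, 860)$category, "exon")       # midpoint 850
  # midpoint 500 bp downstream of the transcript end on the minus strand
  # (genomic -500) cannot exist; use within the TTS window instead
  expect_equal(rec(0, 100)$category, "tts")          # midpoint 50, d = -50
  # promoter wins over exon when windows overlap: midpoint at 950 is inside
  # the second exon and 50 bp upstream of the TSS
  expect_equal(rec(900, 1000)$category, "promoter_tss")
  # distance is 0 at the TSS regardless of strand
  at_tss <- rec(900, 1100)  # midpoint 1000 = TSS
  expect_equal(at_tss$tss_distance, 0)
  plus <- read_gene_models(withr::local_tempfile(
    lines = bed12_line("chr1", 500, 900, "gp", "+", rbind(c(500, 900)))))
  at_plus_tss <- annotate_peak(list(chrom = "chr1", start = 400, end = 600),
                               plus)
  expect_equal(at_plus_tss$tss_distance, 0)
})

test_that("peaks on gene-free chromosomes are intergenic with no gene", {
  g <- two_exon_minus()
  r <- annotate_peak(list(chrom = "chr9", start = 0, end = 100), g)
  expect_equal(r$category, "intergenic")
  expect_true(is.na(r$nearest_gene))
  expect_true(is.na(r$tss_distance))
})

test_that("nearest TSS minimises distance with lexicographic ties", {
  lines <- c(bed12_line("chr1", 1000, 2000, "gB", "+", rbind(c(1000, 2000))),
             bed12_line("chr1", 3000, 4000, "gA", "-", rbind(c(3000, 4000))))
  g <- read_gene_models(withr::local_tempfile(lines = lines))
  # midpoint 2500: equidistant from TSS gB (1000 -> 1500) and gA (4000 -> 1500)
  r <- annotate_peak(list(chrom = "chr1", start = 2400, end = 2600), g)
  expect_equal(r$nearest_gene, "gA")
  # closer to gB's TSS
  r2 <- annotate_peak(list(chrom = "chr1", start = 1100, end = 1300), g)
  expect_equal(r2$nearest_gene, "gB")
  expect_equal(r2$tss_distance, 200)   # downstream of a + TSS is positive
  r3 <- annotate_peak(list(chrom = "chr1", start = 4100, end = 4300), g)
  expect_equal(r3$nearest_gene, "gA")
  expect_equal(r3$tss_distance, -200)  # upstream of a - TSS
})

test_that("category assignment is invariant under a coordinate mirror", {
  L <- 50000
  set.seed(41)
  for (rep in 1:10) {
    # genes and odd-length peaks (half-integer midpoints avoid boundaries)
    n_g <- 4
    gs <- sort(sample(seq(2000, L - 8000, by = 100), n_g))
    lines <- vapply(seq_len(n_g), function(i) {
      s <- gs[i]; e <- s + 3000
      bed12_line("chr1", s, e, sprintf("g%02d", i),
                 sample(c("+", "-"), 1),
                 rbind(c(s, s + 1000), c(e - 1000, e)))
    }, "")
    g <- read_gene_models(withr::local_tempfile(lines = lines))
    starts <- sample(seq(0, L - 1001), 60)
    peaks <- peak_set(data.frame(chrom = "chr1", start = starts,
                                 end = starts + 1001,
                                 name = sprintf("p%02d", 1:60)))
    fwd <- annotate_peaks(peaks, g)
    # mirror everything about the chromosome midpoint
    mg <- g
    mg$start <- L - g$end
    mg$end <- L - g$start
    mg$strand <- ifelse(g$strand == "+", "-", "+")
    mg$exons <- lapply(g$exons, function(ex)
      cbind(start = rev(L - ex[, "end"]), end = rev(L - ex[, "start"])))
    mpeaks <- peak_set(data.frame(chrom = "chr1",
                                  start = L - (starts + 1001),
                                  end = L - starts,
                                  name = sprintf("p%02d", 1:60)))
    mir <- annotate_peaks(mpeaks, mg)
    expect_equal(mir$category[match(fwd$peak_name, mir$peak_name)],
                 fwd$category)
  }
})

test_that("annotation breakdowns count and percentage every category", {
  rec <- data.frame(peak_name = c("a", "b", "c", "d"),
                    category = c("intron", "intron", "intergenic",
                                 "intergenic"),
                    stringsAsFactors = FALSE)
  bd <- annotation_breakdown(rec)
  expect_equal(sum(bd$percentage), 100)
  expect_equal(bd$percentage[bd$category == "intron"], 50)
  expect_equal(bd$percentage[bd$category == "intergenic"], 50)
  one <- annotation_breakdown(rec[1, , drop = FALSE])
  expect_equal(one$percentage[one$category == "intron"], 100)
  expect_error(annotation_breakdown(rec[0, , drop = FALSE]), "no annotation")
})

test_that("gene-list overlap computes the three Venn counts", {
  rec <- data.frame(peak_name = c("p1", "p2"),
                    nearest_gene = c("g1", "g2"),
                    tss_distance = c(100, -20000), stringsAsFactors = FALSE)
  ov <- gene_list_overlap(rec, c("g2", "g3"))
  expect_equal(ov$intersection, "g2")
  expect_equal(unname(ov$counts), c(1, 1, 1))
  disjoint <- gene_list_overlap(rec, c("g7", "g8"))
  expect_length(disjoint$intersection, 0)
  # the distance cap removes p2's gene from the associated set
  capped <- gene_list_overlap(rec, c("g2", "g3"), max_tss_distance = 1000)
  expect_equal(capped$associated, "g1")
  expect_equal(unname(capped$counts), c(1, 2, 0))
  set.seed(42)
  for (i in 1:50) {
    universe <- sprintf("gene%03d", 1:500)
    assoc <- sample(universe, 50)
    de <- sample(universe, 50)
    rec <- data.frame(peak_name = paste0("p", seq_along(assoc)),
                      nearest_gene = assoc, tss_distance = 0,
                      stringsAsFactors = FALSE)
    ov <- gene_list_overlap(rec, de)
    expect_equal(unname(ov$counts),
                 c(length(setdiff(assoc, de)), length(setdiff(de, assoc)),
                   length(intersect(assoc, de))))
    expect_identical(ov$intersection, sort(intersect(assoc, de)))
  }
})
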